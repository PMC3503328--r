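# Time-resolved Monte Carlo forward model: wide-field pattern sources,
# transmission detector array, adjoint detector sources, and the analytic
# homogeneous-medium oracle.

#' Transmission detector array on the exit face
#'
#' A fixed rectangular array of square detector patches (edge = pitch,
#' contiguous) centered on the spine, on the face opposite the illumination.
#' Detector index runs Y-fastest: `d = (jz - 1) * ny + jy`.
#'
#' @param ny detectors across Y (default 12)
#' @param nz detectors along Z (default 13)
#' @param pitch_mm center-to-center separation, mm (default 2.48)
#' @return object of class `fmt_detgrid` with world-frame patch centers
#' @export
detector_grid <- function(ny = 12, nz = 13, pitch_mm = 2.48) {
  stopifnot(ny >= 1, nz >= 1, pitch_mm > 0)
  structure(list(
    ny = as.integer(ny), nz = as.integer(nz), pitch_mm = pitch_mm,
    y_centers = (seq_len(ny) - (ny + 1) / 2) * pitch_mm,
    z_centers = (seq_len(nz) - (nz + 1) / 2) * pitch_mm
  ), class = "fmt_detgrid")
}

#' Wide-field illumination pattern for one sliding position
#'
#' A uniform rectangle on the entry face (X-min side, photons travel +X),
#' covering half the spine diameter transversely by default and tiling the
#' scan range along Z by uniform translation over `n_patterns` positions.
#'
#' @param pattern pattern index in `1:n_patterns`
#' @param n_patterns number of sliding positions (default 12)
#' @param scan_length_mm longitudinal scan range, mm (defaults to the
#'   phantom cylinder length)
#' @param width_mm transverse (Y) extent of the rectangle, mm
#' @return object of class `fmt_source` (type "rect", world frame)
#' @export
pattern_source <- function(pattern, n_patterns = 12, scan_length_mm = 45,
                           width_mm = 10) {
  stopifnot(pattern >= 1, pattern <= n_patterns)
  h <- scan_length_mm / n_patterns
  z0 <- -scan_length_mm / 2 + (pattern - 1) * h
  structure(list(type = "rect", side = "xmin",
                 y0 = -width_mm / 2, y1 = width_mm / 2,
                 z0 = z0, z1 = z0 + h,
                 pattern = as.integer(pattern)), class = "fmt_source")
}

#' Isotropic point source inside the medium (validation geometry)
#' @param pos_mm (x, y, z) position, world frame, mm
#' @return object of class `fmt_source` (type "point")
#' @export
point_source <- function(pos_mm) {
  structure(list(type = "point", pos = as.numeric(pos_mm)),
            class = "fmt_source")
}

#' Adjoint source on a detector patch (exit face, photons travel -X)
#' @param y_range,z_range extents of the patch rectangle, world frame, mm
#' @return object of class `fmt_source`
#' @export
adjoint_source <- function(y_range, z_range) {
  structure(list(type = "rect", side = "xmax",
                 y0 = y_range[1], y1 = y_range[2],
                 z0 = z_range[1], z1 = z_range[2]), class = "fmt_source")
}

# label-ordered optical property matrix in 1/mm for the C++ core
.props_matrix <- function(phantom) {
  p <- phantom$properties[names(fmt_labels)]
  t(vapply(p, function(o) c(o$mu_a / 10, o$mu_s / 10, o$n), numeric(3)))
}

#' Run one Monte Carlo transport simulation
#'
#' Launches photons from a pattern, adjoint-patch or internal point source,
#' propagates them with exponential path sampling against the local total
#' interaction coefficient, isotropic scattering, albedo absorption
#' weighting, Fresnel reflection/refraction at refractive-index steps, and
#' Russian roulette; accumulates time-resolved fluence on tissue voxels
#' (path-length estimator, per launched photon) and detector-patch exit
#' TPSFs on native time bins.
#'
#' @param phantom an `fmt_phantom` (laboratory frame)
#' @param source an `fmt_source`
#' @param n_photons photon budget (>= 1e3)
#' @param seed integer RNG seed (own xoshiro stream; independent of R's RNG)
#' @param nt number of native time bins
#' @param dt_ns native bin width, ns (default 0.04 = 40 ps)
#' @param detectors an [detector_grid()] or NULL
#' @param record_fluence accumulate the internal fluence map?
#' @param roulette_threshold,roulette_p Russian roulette weight threshold and
#'   survival probability
#' @return list with `fluence` (tissue voxels x nt, or NULL), `det_tpsf`
#'   (patches x nt, or NULL), `tallies` (energy bookkeeping per launched
#'   photon), `tissue_idx`, `dt_ns`, `nt`
#' @export
run_mc <- function(phantom, source, n_photons, seed, nt = 128, dt_ns = 0.04,
                   detectors = NULL, record_fluence = TRUE,
                   roulette_threshold = 1e-4, roulette_p = 0.1) {
  stopifnot(inherits(phantom, "fmt_phantom"), inherits(source, "fmt_source"))
  if (n_photons < 1e3) stop("n_photons must be at least 1e3")
  d <- dim(phantom$labels)
  v <- phantom$voxel_mm
  off <- d * v / 2 # world -> grid corner frame

  src <- if (source$type == "rect") {
    list(type = "rect",
         dir = if (source$side == "xmin") 1 else -1,
         y0 = source$y0 + off[2], y1 = source$y1 + off[2],
         z0 = source$z0 + off[3], z1 = source$z1 + off[3])
  } else {
    list(type = "point", pos = as.numeric(source$pos) + off)
  }
  if (src$type == "rect") {
    if (src$y0 < 0 || src$y1 > d[2] * v || src$z0 < 0 || src$z1 > d[3] * v)
      stop("source rectangle lies outside the phantom face")
  }

  det <- list()
  if (!is.null(detectors)) {
    stopifnot(inherits(detectors, "fmt_detgrid"))
    det <- list(x_plane = d[1] * v,
                y0 = detectors$y_centers[1] + off[2],
                z0 = detectors$z_centers[1] + off[3],
                pitch = detectors$pitch_mm,
                ny = detectors$ny, nz = detectors$nz)
  }

  tidx <- tissue_indices(phantom)
  trow <- rep.int(-1L, prod(d))
  trow[tidx] <- seq_along(tidx) - 1L

  out <- .mc_run_cpp(as.integer(phantom$labels), as.integer(d), v,
                     .props_matrix(phantom), src, dt_ns, as.integer(nt), det,
                     trow, length(tidx), as.double(n_photons),
                     as.double(seed), roulette_threshold, roulette_p,
                     record_fluence)
  # per-run energy bookkeeping: launched = absorbed + exited + time cutoff
  # + net roulette weight change, exactly (floating summation error only)
  tal <- out$tallies
  bal <- tal[["absorbed"]] + tal[["exited"]] + tal[["cutoff"]] +
    tal[["roulette_net"]]
  if (abs(bal - tal[["launched"]]) > 1e-6 * tal[["launched"]])
    stop(sprintf("energy conservation violated: |1 - %.9f| > 1e-6", bal))
  out$tissue_idx <- tidx
  out$dt_ns <- dt_ns
  out$nt <- as.integer(nt)
  out$n_photons <- n_photons
  out$seed <- seed
  out
}

#' Analytic time-domain diffusion Green's function, infinite medium
#'
#' Fluence rate at distance `r` and time `t` after an instantaneous isotropic
#' unit-energy point source, in the diffusion approximation with
#' `D = 1/(3 (mu_a + mu_sp))`: the independent oracle for the Monte Carlo
#' transport in the homogeneous limit.
#'
#' @param mu_a absorption coefficient, 1/mm
#' @param mu_sp reduced scattering coefficient, 1/mm (valid for mu_sp >> mu_a)
#' @param n refractive index
#' @param r source-point distance, mm
#' @param t time after the pulse, ns (> 0; vectorized)
#' @return fluence rate, 1/(mm^2 ns)
#' @export
analytic_tpsf <- function(mu_a, mu_sp, n, r, t) {
  if (any(t <= 0)) stop("t must be positive")
  v <- .c_mm_ns / n
  D <- 1 / (3 * (mu_a + mu_sp))
  v * (4 * pi * D * v * t)^(-3 / 2) * exp(-r^2 / (4 * D * v * t) - mu_a * v * t)
}

#' Simulate the excitation scan of one view
#'
#' One Monte Carlo run per sliding pattern; returns the detector TPSFs
#' stacked into a measurement x time matrix (measurement order: pattern-major,
#' detector-fastest) and the internal excitation Green's function per pattern.
#' Per-pattern seeds derive deterministically from `(seed, pattern)`.
#'
#' @param phantom laboratory-frame `fmt_phantom`
#' @param n_photons photons per pattern
#' @param seed base seed for the view
#' @param detectors an [detector_grid()]
#' @param n_patterns number of sliding patterns
#' @param pattern_width_mm transverse pattern extent, mm
#' @param nt,dt_ns native time axis
#' @return list `tpsf` (n_patterns * n_det x nt), `fluence` (list of tissue x
#'   nt matrices), `tallies` (per pattern), plus axis metadata
#' @export
simulate_excitation <- function(phantom, n_photons, seed,
                                detectors = detector_grid(),
                                n_patterns = 12, pattern_width_mm = 10,
                                nt = 128, dt_ns = 0.04) {
  ndet <- detectors$ny * detectors$nz
  counts <- matrix(0, n_patterns * ndet, nt)
  flu <- vector("list", n_patterns)
  tal <- vector("list", n_patterns)
  scan_len <- phantom$geometry$length_mm
  for (p in seq_len(n_patterns)) {
    srcp <- pattern_source(p, n_patterns, scan_length_mm = scan_len,
                           width_mm = pattern_width_mm)
    mc <- run_mc(phantom, srcp, n_photons, derive_seed(seed, 101L, p),
                 nt = nt, dt_ns = dt_ns, detectors = detectors)
    counts[(p - 1) * ndet + seq_len(ndet), ] <- mc$det_tpsf
    flu[[p]] <- mc$fluence
    tal[[p]] <- mc$tallies
  }
  list(tpsf = counts, fluence = flu, tallies = tal,
       tissue_idx = tissue_indices(phantom), nt = nt, dt_ns = dt_ns,
       n_patterns = n_patterns, n_detectors = ndet)
}

#' Group the detector array into adjoint super-patches
#'
#' Adjoint Green's functions are computed per rectangular group of detectors
#' (cost control: one Monte Carlo run per group instead of per detector);
#' every detector maps to the group containing it.
#'
#' @param detectors an [detector_grid()]
#' @param group_y,group_z detectors per group along Y and Z (default 4 x 4)
#' @return list `patches` (list of y/z ranges, world frame) and `of_detector`
#'   (integer patch id per detector)
#' @export
superpatch_layout <- function(detectors, group_y = 4, group_z = 4) {
  gy <- ceiling(detectors$ny / group_y)
  gz <- ceiling(detectors$nz / group_z)
  half <- detectors$pitch_mm / 2
  patches <- list()
  of_det <- integer(detectors$ny * detectors$nz)
  for (bz in seq_len(gz)) for (by in seq_len(gy)) {
    pid <- (bz - 1) * gy + by
    jy <- ((by - 1) * group_y + 1):min(by * group_y, detectors$ny)
    jz <- ((bz - 1) * group_z + 1):min(bz * group_z, detectors$nz)
    patches[[pid]] <- list(
      y_range = range(detectors$y_centers[jy]) + c(-half, half),
      z_range = range(detectors$z_centers[jz]) + c(-half, half))
    for (k in jz) of_det[(k - 1) * detectors$ny + jy] <- pid
  }
  list(patches = patches, of_detector = of_det,
       n_patches = gy * gz)
}

#' Adjoint emission Green's function of one detector patch
#'
#' Runs the Monte Carlo with the detector patch acting as a wide-field
#' surface source on the exit face (reciprocity), at the emission-wavelength
#' optical properties (equal to excitation by default).
#'
#' @param phantom laboratory-frame `fmt_phantom`
#' @param patch list with `y_range`, `z_range` (world mm) as produced by
#'   [superpatch_layout()]
#' @param n_photons photon budget
#' @param seed integer seed
#' @param nt,dt_ns native time axis
#' @return fluence matrix (tissue voxels x nt)
#' @export
adjoint_emission_greens <- function(phantom, patch, n_photons, seed,
                                    nt = 128, dt_ns = 0.04) {
  src <- adjoint_source(patch$y_range, patch$z_range)
  mc <- run_mc(phantom, src, n_photons, seed, nt = nt, dt_ns = dt_ns,
               detectors = NULL)
  mc$fluence
}

#' Fluorescence detector TPSFs from excitation and adjoint Green's functions
#'
#' Per measurement (pattern, detector), the emission TPSF is the tissue-voxel
#' sum of `eta(r)` times the discrete temporal convolution of the excitation
#' Green's function, the unit-area exponential lifetime kernel, and the
#' adjoint emission Green's function of the detector's patch, scaled by the
#' voxel volume.
#'
#' @param eta fluorescence yield per tissue voxel (same row order as the
#'   Green's function matrices)
#' @param tau_ns fluorophore lifetime, ns
#' @param gx list of excitation fluence matrices (tissue x nt), one per
#'   pattern
#' @param gm list of adjoint fluence matrices (tissue x nt), one per patch
#' @param patch_of_detector integer patch id per detector
#' @param voxel_mm voxel size, mm
#' @param dt_ns native bin width, ns
#' @return matrix (n_patterns * n_detectors x nt) of emission TPSFs
#' @export
simulate_emission <- function(eta, tau_ns, gx, gm, patch_of_detector,
                              voxel_mm, dt_ns = 0.04) {
  nt <- ncol(gx[[1]])
  nvox <- nrow(gx[[1]])
  for (g in c(gx, gm)) {
    if (ncol(g) != nt || nrow(g) != nvox)
      stop("mismatched grids or time axes between Green's functions")
  }
  if (length(eta) != nvox) stop("eta length does not match the voxel grid")
  ndet <- length(patch_of_detector)
  np <- length(gx)
  supp <- which(eta > 0)
  out <- matrix(0, np * ndet, nt)
  if (length(supp) == 0) return(out)
  es <- eta[supp]
  vvol <- voxel_mm^3
  for (p in seq_len(np)) {
    A <- .exp_filter_cpp(gx[[p]][supp, , drop = FALSE], dt_ns, tau_ns)
    for (s in unique(patch_of_detector)) {
      f <- .emission_tpsf_cpp(A, gm[[s]][supp, , drop = FALSE], es) * vvol
      dets <- which(patch_of_detector == s)
      out[(p - 1) * ndet + dets, ] <-
        matrix(f, length(dets), nt, byrow = TRUE)
    }
  }
  out
}
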