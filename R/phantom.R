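# Synthetic spine phantom: labeled voxel grid, optical properties,
# fluorescent inclusion, and 90-degree view transforms.

#' Region label codes used in phantom label arrays
#'
#' Integer codes: BACKGROUND = 0 (air, non-tissue), BONE = 1,
#' SPINAL_CORD = 2, DISC = 3.
#' @export
fmt_labels <- c(BACKGROUND = 0L, BONE = 1L, SPINAL_CORD = 2L, DISC = 3L)

#' Optical properties of one tissue region
#'
#' @param mu_a absorption coefficient, 1/cm
#' @param mu_s reduced scattering coefficient mu_s', 1/cm (simulation uses the
#'   similarity relation with anisotropy g = 0)
#' @param g scattering anisotropy, in `[0, 1)`
#' @param n refractive index (> 0; 1 for air, 1.37 for tissue)
#' @return an object of class `fmt_optical`
#' @export
optical_properties <- function(mu_a, mu_s, g = 0, n = 1.37) {
  stopifnot(mu_a >= 0, mu_s >= 0, g >= 0, g < 1, n > 0)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "fmt_optical")
}

#' Literature optical properties of the segmented spine regions
#'
#' Absorption and reduced scattering coefficients (1/cm) for bone, spinal
#' cord and intervertebral disc, plus a non-scattering air background.
#' Tissue refractive index defaults to 1.37, air to 1.0.
#'
#' @return named list of [optical_properties()] keyed by region label name
#' @export
#' @examples
#' optical_property_table()$BONE$mu_a # 0.04 cm^-1
optical_property_table <- function() {
  list(
    BACKGROUND  = optical_properties(0,     0,   g = 0, n = 1.0),
    BONE        = optical_properties(0.04,  12),
    SPINAL_CORD = optical_properties(0.121, 8.9),
    DISC        = optical_properties(0.008, 5)
  )
}

# voxel-center world coordinates along one axis (mm), centered on the grid
.axis_centers <- function(n, voxel_mm) (seq_len(n) - (n + 1) / 2) * voxel_mm

#' Build the synthetic spine phantom
#'
#' An approximately cylindrical bone body (axis along Z, the rotation axis)
#' with an axial spinal-cord channel and one transverse intervertebral-disc
#' slab separating two vertebrae. Labels partition the cylinder support;
#' the fluorescence yield map starts at zero (see [place_inclusion()]).
#'
#' @param voxel_mm isotropic voxel size, mm (in (0, 2])
#' @param diameter_mm cylinder diameter, mm
#' @param length_mm cylinder length along Z, mm
#' @param disc_thickness_mm transverse disc slab thickness, mm (must span at
#'   least two voxels)
#' @param cord_diameter_mm spinal-cord channel diameter, mm
#' @param disc_center_mm Z position of the disc slab center, mm
#' @param margin_mm air margin around the cylinder, mm (wide enough to
#'   contain the detector array footprint)
#' @param properties region optical properties, as [optical_property_table()]
#' @param tau_ns fluorophore lifetime, ns
#' @return an object of class `fmt_phantom`: label array, yield array `eta`,
#'   properties, voxel size and geometry metadata
#' @export
build_spine_phantom <- function(voxel_mm = 0.5, diameter_mm = 20,
                                length_mm = 45, disc_thickness_mm = 4,
                                cord_diameter_mm = 4, disc_center_mm = 0,
                                margin_mm = 5,
                                properties = optical_property_table(),
                                tau_ns = 0.5) {
  if (voxel_mm <= 0 || voxel_mm > 2) stop("voxel_mm must be in (0, 2]")
  if (disc_thickness_mm < 2 * voxel_mm)
    stop("voxel size too large to resolve the disc (< 2 voxels across)")
  mvox <- max(1L, as.integer(ceiling(margin_mm / voxel_mm)))
  nxy <- as.integer(ceiling(diameter_mm / voxel_mm)) + 2L * mvox
  nz <- as.integer(ceiling(length_mm / voxel_mm)) + 2L * mvox
  xc <- .axis_centers(nxy, voxel_mm)
  zc <- .axis_centers(nz, voxel_mm)

  r2 <- outer(xc^2, xc^2, `+`)                  # nxy x nxy
  in_circle <- r2 <= (diameter_mm / 2)^2
  in_cord <- r2 < (cord_diameter_mm / 2)^2
  in_len <- abs(zc) <= length_mm / 2
  in_disc_z <- zc >= disc_center_mm - disc_thickness_mm / 2 &
    zc < disc_center_mm + disc_thickness_mm / 2

  labels <- array(fmt_labels[["BACKGROUND"]], dim = c(nxy, nxy, nz))
  for (k in which(in_len)) {
    sl <- matrix(fmt_labels[["BACKGROUND"]], nxy, nxy)
    sl[in_circle] <- if (in_disc_z[k]) fmt_labels[["DISC"]] else
      fmt_labels[["BONE"]]
    sl[in_circle & in_cord] <- fmt_labels[["SPINAL_CORD"]]
    labels[, , k] <- sl
  }

  structure(list(
    labels = labels,
    eta = array(0, dim = dim(labels)),
    tau_ns = tau_ns,
    voxel_mm = voxel_mm,
    properties = properties,
    geometry = list(diameter_mm = diameter_mm, length_mm = length_mm,
                    disc_thickness_mm = disc_thickness_mm,
                    cord_diameter_mm = cord_diameter_mm,
                    disc_center_mm = disc_center_mm, margin_mm = margin_mm),
    view = list(index = 1L, angle_deg = 0)
  ), class = "fmt_phantom")
}

#' @export
print.fmt_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("fmt_phantom: %d x %d x %d voxels at %.2f mm\n",
              d[1], d[2], d[3], x$voxel_mm))
  tab <- table(factor(x$labels, levels = fmt_labels,
                      labels = names(fmt_labels)))
  cat("  region voxels:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  eta > 0 voxels: %d; tau = %.2f ns; view angle %g deg\n",
              sum(x$eta > 0), x$tau_ns, x$view$angle_deg))
  invisible(x)
}

#' World coordinates (mm) of all voxel centers, spine frame
#' @param phantom an `fmt_phantom`
#' @return list with vectors `x`, `y`, `z`
#' @export
voxel_coordinates <- function(phantom) {
  d <- dim(phantom$labels)
  list(x = .axis_centers(d[1], phantom$voxel_mm),
       y = .axis_centers(d[2], phantom$voxel_mm),
       z = .axis_centers(d[3], phantom$voxel_mm))
}

#' Place a cubic fluorescent inclusion inside the disc
#'
#' The cube is snapped to the voxel grid (its faces to voxel faces), so the
#' discrete support volume is exactly `round(edge/voxel)^3 * voxel^3`; every
#' supporting voxel must carry the DISC label.
#'
#' @param phantom an `fmt_phantom`
#' @param center_mm requested cube center (x, y, z), mm, spine frame
#' @param edge_mm cube edge, mm (multiple of the voxel size for an exact
#'   support volume)
#' @param yield_value effective fluorescence yield eta on the support
#' @param tau_ns fluorophore lifetime, ns
#' @return a new `fmt_phantom` with `eta` set on the cube support
#' @export
place_inclusion <- function(phantom, center_mm = c(4, 0, 0), edge_mm = 3,
                            yield_value = 0.1, tau_ns = 0.5) {
  stopifnot(inherits(phantom, "fmt_phantom"), edge_mm > 0, yield_value >= 0,
            tau_ns > 0)
  v <- phantom$voxel_mm
  d <- dim(phantom$labels)
  ne <- max(1L, as.integer(round(edge_mm / v)))
  idx <- vector("list", 3)
  for (a in 1:3) {
    centers <- .axis_centers(d[a], v)
    left0 <- centers[1] - v / 2
    i_lo <- as.integer(floor((center_mm[a] - edge_mm / 2 - left0) / v + 0.5)) + 1L
    i_hi <- i_lo + ne - 1L
    if (i_lo < 1L || i_hi > d[a])
      stop("inclusion extends outside the phantom grid")
    idx[[a]] <- i_lo:i_hi
  }
  sel_labels <- phantom$labels[idx[[1]], idx[[2]], idx[[3]]]
  if (!all(sel_labels == fmt_labels[["DISC"]]))
    stop("inclusion must lie entirely within the DISC region")
  phantom$eta[idx[[1]], idx[[2]], idx[[3]]] <- yield_value
  phantom$tau_ns <- tau_ns
  phantom
}

#' View transform: rotation about the spine (Z) axis
#'
#' The acquisition rotates the specimen in 90-degree steps for four views.
#' An optional angular jitter models the holder's locking error; with jitter
#' the rotation is applied by nearest-neighbor resampling instead of an exact
#' grid permutation.
#'
#' @param index view index 1-4
#' @param angle_deg rotation angle about Z; defaults to `(index - 1) * 90`
#' @param jitter_deg angular jitter added to the nominal angle, degrees
#' @return an object of class `fmt_view`
#' @export
view_transform <- function(index, angle_deg = (index - 1) * 90,
                           jitter_deg = 0) {
  stopifnot(index >= 1)
  structure(list(index = as.integer(index), angle_deg = angle_deg,
                 jitter_deg = jitter_deg), class = "fmt_view")
}

# one exact 90-degree rotation about Z: world (x, y) -> (y, -x)
.rot90_once <- function(a) {
  b <- aperm(a, c(2, 1, 3))
  b[, dim(b)[2]:1, , drop = FALSE]
}

# rotate a 3-D array k * 90 degrees about Z
.rot90_array <- function(a, k) {
  k <- ((k %% 4) + 4) %% 4
  while (k > 0) { a <- .rot90_once(a); k <- k - 1 }
  a
}

# permutation p with lab[p[s]] = spine[s] (linear indices) for k 90-deg steps
.rot90_perm <- function(dims, k) {
  n <- prod(dims)
  idx <- array(seq_len(n), dim = dims)
  lab_of <- as.vector(.rot90_array(idx, k)) # lab position -> spine index
  p <- integer(n)
  p[lab_of] <- seq_len(n)
  p
}

#' Rotate a phantom into the laboratory frame of one acquisition view
#'
#' Multiples of 90 degrees are exact grid permutations (the grid is square in
#' X-Y); the transform metadata is recorded so reconstructions can be mapped
#' back to the fixed spine frame. Non-multiples are only allowed with
#' `jitter_deg != 0` and use nearest-neighbor resampling.
#'
#' @param phantom an `fmt_phantom` in the spine frame
#' @param view an [view_transform()]
#' @return the rotated `fmt_phantom` (laboratory frame)
#' @export
apply_view <- function(phantom, view) {
  stopifnot(inherits(phantom, "fmt_phantom"), inherits(view, "fmt_view"))
  ang <- view$angle_deg + view$jitter_deg
  d <- dim(phantom$labels)
  if (view$jitter_deg == 0) {
    if (abs(ang %% 90) > 1e-9)
      stop("rotation angle must be a multiple of 90 degrees unless jitter is enabled")
    k <- as.integer(round(ang / 90))
    phantom$labels <- .rot90_array(phantom$labels, k)
    phantom$eta <- .rot90_array(phantom$eta, k)
  } else {
    if (d[1] != d[2]) stop("jittered rotation requires a square X-Y grid")
    th <- ang * pi / 180
    xc <- .axis_centers(d[1], phantom$voxel_mm)
    # target (x', y') pulls from source (x, y) = M(-theta) (x', y')
    gx <- matrix(xc, d[1], d[2])
    gy <- matrix(xc, d[1], d[2], byrow = TRUE)
    sx <- cos(th) * gx - sin(th) * gy
    sy <- sin(th) * gx + cos(th) * gy
    ix <- pmin(pmax(round(sx / phantom$voxel_mm + (d[1] + 1) / 2), 1), d[1])
    iy <- pmin(pmax(round(sy / phantom$voxel_mm + (d[2] + 1) / 2), 1), d[2])
    lin <- cbind(as.vector(ix), as.vector(iy))
    for (k in seq_len(d[3])) {
      sl <- phantom$labels[, , k]
      phantom$labels[, , k] <- matrix(sl[lin], d[1], d[2])
      se <- phantom$eta[, , k]
      phantom$eta[, , k] <- matrix(se[lin], d[1], d[2])
    }
  }
  phantom$view <- list(index = view$index, angle_deg = view$angle_deg,
                       jitter_deg = view$jitter_deg)
  phantom
}

#' Inverse of a view transform
#' @param view an `fmt_view`
#' @return the `fmt_view` undoing it
#' @export
invert_view <- function(view) {
  view_transform(view$index, angle_deg = -view$angle_deg,
                 jitter_deg = -view$jitter_deg)
}

#' Linear indices of tissue (non-background) voxels, fixed ordering
#' @param phantom an `fmt_phantom`
#' @return integer vector of linear voxel indices
#' @export
tissue_indices <- function(phantom) {
  which(as.vector(phantom$labels) != fmt_labels[["BACKGROUND"]])
}

#' Centroid (mm) of the true inclusion support
#' @param phantom an `fmt_phantom` with `eta > 0` somewhere
#' @return numeric (x, y, z) in mm, spine frame
#' @export
inclusion_centroid <- function(phantom) {
  centroid(phantom$eta > 0, voxel_mm = phantom$voxel_mm)
}
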