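# Sensitivity (Jacobian) assembly by the time forward-adjoint method, in the
# Born-normalized formulation, for CW or time-gated data.

#' Homogenize a phantom's optical model
#'
#' Assigns the bone optical properties to every tissue region (the
#' homogeneous-Jacobian model); region labels and geometry are retained for
#' evaluation.
#'
#' @param phantom an `fmt_phantom`
#' @return the phantom with a single tissue property set, tagged
#'   `optical_model = "homogeneous"`
#' @export
homogenize <- function(phantom) {
  stopifnot(inherits(phantom, "fmt_phantom"))
  bone <- phantom$properties$BONE
  phantom$properties$SPINAL_CORD <- bone
  phantom$properties$DISC <- bone
  attr(phantom, "optical_model") <- "homogeneous"
  phantom
}

# head cumulative sums per row: Qc[, m] = sum_{u <= m} G[, u]
.head_cumsum <- function(G) {
  nt <- ncol(G)
  U <- matrix(0, nt, nt)
  U[upper.tri(U, diag = TRUE)] <- 1
  G %*% U
}

#' Assemble a Born-normalized sensitivity matrix for one view
#'
#' Row (m, g): the derivative of the Born-normalized datum of measurement m
#' (pattern, detector) at gate g (or its CW integral) with respect to the
#' fluorescence yield of each tissue voxel:
#' `theta / U0(m) * [Gx (*) K_tau (*) Gm](gate window) * voxel volume`,
#' evaluated from the excitation Green's function of the measurement's
#' pattern and the adjoint emission Green's function of its detector patch.
#' Rows of masked measurements are omitted.
#'
#' @param gx list of excitation fluence matrices (tissue voxels x nt), one
#'   per pattern
#' @param gm list of adjoint fluence matrices, one per detector patch
#' @param u0 time-integrated excitation per measurement
#'   (pattern-major, detector-fastest; length n_patterns * n_detectors)
#' @param patch_of_detector integer patch id per detector
#' @param tau_ns fluorophore lifetime, ns
#' @param voxel_mm voxel size, mm
#' @param data_type "cw" or "tg"
#' @param gate_starts for "tg": list (per measurement) of integer 0-based
#'   gate start bins (selected early or late gates)
#' @param gate_width_bins gate width in native bins (default 300/40 ps)
#' @param mask logical per measurement; FALSE rows are omitted
#' @param theta system constant
#' @param dt_ns native bin width, ns
#' @param block optional external single-precision block (from
#'   `.jblock_create_cpp`) to fill instead of returning a dense matrix
#' @param row_offset 0-based first destination row when filling a block
#' @return list: `J` (dense rows x voxels matrix, or NULL when filling a
#'   block) and `rows`, a data.frame (measurement, pattern, detector,
#'   gate_start_bin) describing each row in order
#' @export
build_jacobian <- function(gx, gm, u0, patch_of_detector, tau_ns, voxel_mm,
                           data_type = c("cw", "tg"), gate_starts = NULL,
                           gate_width_bins = 8L, mask = NULL, theta = 1,
                           dt_ns = 0.04, block = NULL, row_offset = 0L) {
  data_type <- match.arg(data_type)
  nt <- ncol(gx[[1]])
  nvox <- nrow(gx[[1]])
  np <- length(gx)
  ndet <- length(patch_of_detector)
  nmeas <- np * ndet
  stopifnot(length(u0) == nmeas)
  for (g in c(gx, gm))
    if (ncol(g) != nt || nrow(g) != nvox) stop("mismatched time axes or grids")
  if (is.null(mask)) mask <- rep(TRUE, nmeas)
  if (data_type == "tg") {
    if (is.null(gate_starts)) stop("gate set empty: gate_starts required for tg")
    stopifnot(length(gate_starts) == nmeas)
  }

  # adjoint-side prefilters, shared across patterns
  Q <- if (data_type == "cw") lapply(gm, .head_cumsum)
       else lapply(gm, .boxcar_cpp, W = as.integer(gate_width_bins))
  conv_offset <- if (data_type == "cw") 0L else
    as.integer(gate_width_bins) - 1L

  rows_m <- integer(0); rows_d <- integer(0); rows_p <- integer(0)
  rows_g <- integer(0)
  nrow_total <- 0L
  plan <- vector("list", np)
  for (p in seq_len(np)) {
    plan_p <- list()
    for (s in unique(patch_of_detector)) {
      dets <- which(patch_of_detector == s)
      chunk <- list()
      for (d in dets) {
        m <- (p - 1L) * ndet + d
        if (!mask[m] || !is.finite(u0[m]) || u0[m] <= 0) next
        starts <- if (data_type == "cw") nt - 1L else
          as.integer(gate_starts[[m]])
        if (length(starts) == 0) next
        chunk[[length(chunk) + 1L]] <- list(m = m, d = d, starts = starts)
        rows_m <- c(rows_m, rep.int(m, length(starts)))
        rows_d <- c(rows_d, rep.int(d, length(starts)))
        rows_p <- c(rows_p, rep.int(p, length(starts)))
        rows_g <- c(rows_g, starts)
        nrow_total <- nrow_total + length(starts)
      }
      plan_p[[as.character(s)]] <- chunk
    }
    plan[[p]] <- plan_p
  }
  if (nrow_total == 0L) stop("no unmasked rows to assemble")

  dense <- is.null(block)
  J <- if (dense) matrix(0, nrow_total, nvox) else NULL
  vvol <- voxel_mm^3
  row_at <- 0L
  for (p in seq_len(np)) {
    A <- .exp_filter_cpp(gx[[p]], dt_ns, tau_ns)
    for (s in unique(patch_of_detector)) {
      chunk <- plan[[p]][[as.character(s)]]
      if (length(chunk) == 0) next
      all_starts <- sort(unique(unlist(lapply(chunk, `[[`, "starts"))))
      C <- .gated_conv_cpp(A, Q[[s]], as.integer(all_starts), conv_offset)
      for (e in chunk) {
        k <- match(e$starts, all_starts)
        scale <- theta * vvol / u0[e$m]
        nr <- length(e$starts)
        if (dense) {
          J[row_at + seq_len(nr), ] <- t(C[, k, drop = FALSE]) * scale
        } else {
          .jblock_fill_cpp(block, C,
                           as.integer(row_offset + row_at + seq_len(nr) - 1L),
                           as.integer(k - 1L), rep(scale, nr))
        }
        row_at <- row_at + nr
      }
    }
  }
  list(J = J,
       rows = data.frame(measurement = rows_m, pattern = rows_p,
                         detector = rows_d,
                         gate_start_bin = if (data_type == "cw")
                           NA_integer_ else rows_g))
}

#' Brute-force finite-difference sensitivity of one voxel
#'
#' Perturbs the yield of a single tissue voxel by `delta_eta`, runs the full
#' emission forward model through [simulate_emission()] and Born
#' normalization, and differences: the independent oracle for
#' [build_jacobian()].
#'
#' @param gx,gm,patch_of_detector,u0,tau_ns,voxel_mm,dt_ns,theta as in
#'   [build_jacobian()]
#' @param measurement measurement index (pattern-major, detector-fastest)
#' @param voxel tissue-voxel row index to perturb
#' @param delta_eta perturbation size (> 0)
#' @param eta0 baseline yield per tissue voxel (default all zero)
#' @param data_type "cw" or "tg"
#' @param gate_start_bin 0-based gate start bin (tg only)
#' @param gate_width_bins gate width in bins
#' @return the finite-difference estimate of the Jacobian entry
#' @export
finite_difference_jacobian <- function(gx, gm, patch_of_detector, u0,
                                       tau_ns, voxel_mm, measurement, voxel,
                                       delta_eta, eta0 = NULL,
                                       data_type = c("cw", "tg"),
                                       gate_start_bin = 0L,
                                       gate_width_bins = 8L,
                                       dt_ns = 0.04, theta = 1) {
  data_type <- match.arg(data_type)
  stopifnot(delta_eta > 0)
  nvox <- nrow(gx[[1]])
  nt <- ncol(gx[[1]])
  if (is.null(eta0)) eta0 <- numeric(nvox)
  val <- function(eta) {
    em <- simulate_emission(eta, tau_ns, gx, gm, patch_of_detector, voxel_mm,
                            dt_ns)
    f <- em[measurement, ]
    y <- if (data_type == "cw") sum(f) else {
      b <- gate_start_bin + seq_len(gate_width_bins)
      sum(f[b[b <= nt]])
    }
    theta * y / u0[measurement]
  }
  eta1 <- eta0
  eta1[voxel] <- eta1[voxel] + delta_eta
  (val(eta1) - val(eta0)) / delta_eta
}
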