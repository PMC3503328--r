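# Iterative least-squares reconstruction of the fluorescence yield, with the
# two-stage early/late-gate scheme and multi-view row stacking.

#' Fixed-iteration least-squares solve (CGLS)
#'
#' Conjugate gradients on the normal equations from an initial guess, run for
#' a fixed number of iterations (early stopping is the only regularization:
#' no priors). The least-squares residual norm is non-increasing per
#' iteration; negative entries are clamped to zero in the returned solution.
#'
#' @param J sensitivity matrix (rows x tissue voxels) or an `fmt_system`
#'   (virtual row-stack of per-view blocks, see [combine_views()])
#' @param y Born-normalized data (for an `fmt_system`, omit: carried by the
#'   system)
#' @param iterations fixed iteration count (default 100)
#' @param initial_guess starting yield per voxel (default zero)
#' @param column_scaling spatially variant sensitivity normalization: the
#'   unknowns are preconditioned by `(column norm)^power`, floored at
#'   `floor_frac` of the largest column norm. This counteracts the surface
#'   bias of unconverged iterations in deep tissue without amplifying
#'   noise-floor columns; the least-squares minimizer is unchanged, only the
#'   iteration path differs. Give as `list(power =, floor_frac =)`, TRUE
#'   (defaults: power 0.5, floor 0.01), or FALSE/NULL (off).
#' @return object of class `fmt_recon`: `eta_hat` (clamped), `eta_raw`,
#'   `resnorm` (length iterations + 1), `iterations`
#' @export
solve_least_squares <- function(J, y = NULL, iterations = 100,
                                initial_guess = NULL,
                                column_scaling = FALSE) {
  stopifnot(iterations >= 0)
  scale_of <- function(cn) {
    opt <- column_scaling
    if (is.null(opt) || isFALSE(opt)) return(numeric(0))
    if (isTRUE(opt)) opt <- list()
    power <- if (is.null(opt$power)) 0.5 else opt$power
    floor_frac <- if (is.null(opt$floor_frac)) 0.01 else opt$floor_frac
    m <- max(cn)
    if (m <= 0) return(numeric(0))
    pmax(cn, floor_frac * m)^power
  }
  if (inherits(J, "fmt_system")) {
    ncols <- J$ncol
    x0 <- if (is.null(initial_guess)) numeric(ncols) else initial_guess
    if (length(J$blocks) == 0) stop("empty system")
    cs <- scale_of(.blocks_colnorms_cpp(J$blocks))
    res <- .cgls_blocks_cpp(J$blocks, J$y, as.integer(iterations), x0, cs)
  } else {
    if (is.null(y)) stop("y required for a dense matrix system")
    if (length(y) != nrow(J)) stop("row count of J must match length of y")
    if (length(y) == 0 || ncol(J) == 0) stop("empty system")
    if (!all(is.finite(J)) || !all(is.finite(y)))
      stop("non-finite entries in the system")
    x0 <- if (is.null(initial_guess)) numeric(ncol(J)) else initial_guess
    cs <- scale_of(sqrt(colSums(J^2)))
    res <- .cgls_dense_cpp(J, y, as.integer(iterations), x0, cs)
  }
  eta <- as.vector(res$x)
  structure(list(eta_hat = pmax(eta, 0), eta_raw = eta,
                 resnorm = res$resnorm, iterations = iterations),
            class = "fmt_recon")
}

#' Continuous-wave reconstruction
#'
#' Single-stage CGLS solve of the CW Born-normalized system from a zero
#' initial guess.
#'
#' @inheritParams solve_least_squares
#' @return an `fmt_recon`
#' @export
reconstruct_cw <- function(J, y = NULL, iterations = 100,
                           column_scaling = FALSE) {
  out <- solve_least_squares(J, y, iterations = iterations,
                             column_scaling = column_scaling)
  out$data_type <- "cw"
  out
}

#' Two-stage time-gated reconstruction
#'
#' Stage 1 solves the early rising-gate system from zero (resolution); its
#' output seeds stage 2, a solve of the late decaying-gate system
#' (quantification). When the early system is empty the late stage runs
#' alone, with a warning.
#'
#' @param J_early,y_early early-gate system (matrix + data, or `fmt_system`
#'   with y = NULL)
#' @param J_late,y_late late-gate system
#' @param iterations fixed iterations per stage
#' @param column_scaling see [solve_least_squares()]
#' @return an `fmt_recon` from stage 2, with `resnorm_early` attached
#' @export
reconstruct_tg <- function(J_early, y_early = NULL, J_late, y_late = NULL,
                           iterations = 100, column_scaling = FALSE) {
  empty_early <- is.null(J_early) ||
    (inherits(J_early, "fmt_system") && length(J_early$blocks) == 0)
  if (empty_early) {
    warning("no valid early gates; falling back to late-gate-only reconstruction")
    out <- solve_least_squares(J_late, y_late, iterations = iterations,
                               column_scaling = column_scaling)
    out$resnorm_early <- numeric(0)
  } else {
    st1 <- solve_least_squares(J_early, y_early, iterations = iterations,
                               column_scaling = column_scaling)
    out <- solve_least_squares(J_late, y_late, iterations = iterations,
                               initial_guess = st1$eta_hat,
                               column_scaling = column_scaling)
    out$resnorm_early <- st1$resnorm
  }
  out$data_type <- "tg"
  out
}

#' Stack per-view systems into one joint system in the spine frame
#'
#' Each per-view block must already have its columns mapped to the fixed
#' spine frame (the assembly reorders Green's-function rows by the inverse
#' view rotation); combining is then row concatenation and a single joint
#' solve.
#'
#' @param blocks list of sensitivity blocks (external single-precision
#'   blocks or dense matrices, one or more per view)
#' @param y list of data vectors, aligned with `blocks`
#' @param views integer view index per block
#' @return object of class `fmt_system`
#' @export
combine_views <- function(blocks, y, views) {
  stopifnot(length(blocks) == length(y), length(views) == length(blocks))
  ncols <- unique(vapply(blocks, function(b) {
    if (is.matrix(b)) ncol(b) else .jblock_dim_cpp(b)[2]
  }, numeric(1)))
  if (length(ncols) != 1)
    stop("inconsistent voxel grids across views after mapping")
  dense <- vapply(blocks, is.matrix, logical(1))
  if (any(dense) && !all(dense))
    stop("cannot mix dense and external blocks")
  if (all(dense) && length(blocks) > 0) {
    J <- do.call(rbind, blocks)
    return(structure(list(J = J, yvec = unlist(y), blocks = list(),
                          y = list(), views = views, ncol = ncols,
                          dense = TRUE), class = "fmt_system_dense"))
  }
  structure(list(blocks = blocks, y = y, views = as.integer(views),
                 ncol = as.integer(ncols)), class = "fmt_system")
}

#' Subset a joint system to the blocks of selected views
#' @param system an `fmt_system`
#' @param views view indices to keep (e.g. `1` or `1:4`)
#' @return an `fmt_system` over the kept blocks
#' @export
subset_views <- function(system, views) {
  keep <- which(system$views %in% views)
  structure(list(blocks = system$blocks[keep], y = system$y[keep],
                 views = system$views[keep], ncol = system$ncol),
            class = "fmt_system")
}

#' Embed a tissue-voxel solution into the full phantom grid
#' @param x solution vector over tissue voxels (spine-frame ordering)
#' @param phantom the spine-frame `fmt_phantom`
#' @return 3-D array with the solution at tissue voxels, zero elsewhere
#' @export
recon_to_volume <- function(x, phantom) {
  vol <- array(0, dim = dim(phantom$labels))
  vol[tissue_indices(phantom)] <- x
  vol
}
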