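# Data types: CW integrals, time gates, early/late gate selection, Poisson
# noise, Born normalization, and the measurement schedule.

#' Time-gate schedule
#'
#' Overlapping rectangular gates: gate k (k = 0, ..., n-1) spans
#' `[k * step, k * step + width)` picoseconds; `n = floor(window / step)`.
#' Defaults give 120 gates of 300 ps at 40 ps intervals over 4.8 ns.
#'
#' @param width_ps gate width, ps
#' @param step_ps gate interval, ps
#' @param window_ps total gating window, ps
#' @return object of class `fmt_gates` with `starts_ps` and counts
#' @export
make_gate_schedule <- function(width_ps = 300, step_ps = 40,
                               window_ps = 4800) {
  if (!(step_ps > 0 && step_ps <= width_ps && step_ps <= window_ps))
    stop("need 0 < step <= width and step <= window")
  n <- floor(window_ps / step_ps)
  structure(list(width_ps = width_ps, step_ps = step_ps,
                 window_ps = window_ps, n_gates = as.integer(n),
                 starts_ps = (seq_len(n) - 1) * step_ps),
            class = "fmt_gates")
}

#' Apply a gate schedule to native-bin TPSFs
#'
#' A native bin belongs to gate k when its start time lies in the gate span
#' (half-open membership by bin start; gates may overlap and then share
#' bins).
#'
#' @param tpsf numeric matrix (measurements x native bins) or vector
#' @param schedule an [make_gate_schedule()]
#' @param bin_ps native bin width, ps (default 40)
#' @return matrix (measurements x gates) of gated values
#' @export
apply_gates <- function(tpsf, schedule, bin_ps = 40) {
  stopifnot(inherits(schedule, "fmt_gates"))
  if (schedule$step_ps %% bin_ps != 0)
    stop("native bin width must divide the gate step")
  if (is.vector(tpsf)) tpsf <- matrix(tpsf, nrow = 1)
  nt <- ncol(tpsf)
  starts_bin <- schedule$starts_ps / bin_ps
  wbins <- ceiling(schedule$width_ps / bin_ps) # bins whose start lies in span
  ind <- matrix(0, nt, schedule$n_gates)
  for (k in seq_len(schedule$n_gates)) {
    b <- (starts_bin[k] + seq_len(wbins)) # 1-based bins in the gate span
    b <- b[b <= nt]
    ind[b, k] <- 1
  }
  tpsf %*% ind
}

#' Continuous-wave value: time integral of the TPSF
#' @param tpsf matrix (measurements x bins) or vector
#' @return numeric vector, one CW value per measurement
#' @export
cw_from_tpsf <- function(tpsf) {
  if (is.vector(tpsf)) sum(tpsf) else rowSums(tpsf)
}

#' Poisson shot noise on expected photon counts
#'
#' Values are scaled so the largest expected count equals `scale`, replaced
#' by Poisson draws, and scaled back. Uses an isolated, seeded RNG stream.
#'
#' @param values non-negative expected values (any shape)
#' @param scale expected counts at the maximum value
#' @param seed integer seed
#' @return noisy values, same shape
#' @export
add_poisson_noise <- function(values, scale, seed) {
  if (any(values < 0)) stop("values must be non-negative")
  stopifnot(scale > 0)
  m <- max(values)
  if (m == 0) return(values)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  noisy <- rpois(length(values), lambda = as.vector(values) / m * scale) *
    (m / scale)
  if (is.matrix(values)) matrix(noisy, nrow(values), ncol(values)) else noisy
}

#' Early rising-edge gates of one gated TPSF
#'
#' Gates strictly before the peak whose value reaches the threshold fraction
#' of the peak (the 25% rising criterion); the peak gate is excluded.
#'
#' @param gated numeric vector of gated values for one measurement
#' @param threshold_fraction rising threshold as a fraction of the peak
#' @return list `gates` (integer indices, 1-based), `valid` (FALSE when the
#'   TPSF is all zero or peaks in the first gate)
#' @export
select_early_gates <- function(gated, threshold_fraction = 0.25) {
  pk <- which.max(gated)
  if (gated[pk] <= 0) return(list(gates = integer(0), valid = FALSE))
  idx <- which(seq_along(gated) < pk &
                 gated >= threshold_fraction * gated[pk])
  list(gates = idx, valid = length(idx) > 0)
}

#' Late falling-edge gate of one gated TPSF
#'
#' First gate after the peak whose value has decayed to at most the threshold
#' fraction of the peak (the 50% decaying criterion). When the tail never
#' falls that far within the window the last gate is used and flagged.
#'
#' @param gated numeric vector of gated values for one measurement
#' @param threshold_fraction decay threshold as a fraction of the peak
#' @return list `gate` (integer index), `valid`, `fallback`
#' @export
select_late_gate <- function(gated, threshold_fraction = 0.5) {
  pk <- which.max(gated)
  if (gated[pk] <= 0)
    return(list(gate = NA_integer_, valid = FALSE, fallback = FALSE))
  cand <- which(seq_along(gated) > pk &
                  gated <= threshold_fraction * gated[pk])
  if (length(cand) == 0)
    return(list(gate = length(gated), valid = TRUE, fallback = TRUE))
  list(gate = cand[1], valid = TRUE, fallback = FALSE)
}

#' Born normalization of fluorescence measurements
#'
#' Divides each fluorescence measurement (CW value or gated values) by the
#' time-integrated excitation of the same source-detector pair, times the
#' system constant Theta (1 in silico). Instrument factors and source
#' strength cancel in this ratio. Measurements whose excitation falls below
#' the floor are masked, not divided.
#'
#' @param emission numeric vector (CW) or matrix (measurements x gates)
#' @param u0 time-integrated excitation per measurement
#' @param theta system calibration constant
#' @param floor minimum valid excitation; default `1e-6 * median(u0[u0 > 0])`
#' @return object of class `fmt_born`: `values` (masked entries NA), `mask`
#'   (TRUE = valid), `u0`, `theta`, `floor`
#' @export
born_normalize <- function(emission, u0, theta = 1, floor = NULL) {
  em <- if (is.vector(emission)) matrix(emission, ncol = 1) else emission
  stopifnot(nrow(em) == length(u0))
  if (is.null(floor)) {
    pos <- u0[u0 > 0]
    floor <- if (length(pos)) 1e-6 * median(pos) else Inf
  }
  mask <- is.finite(u0) & u0 >= floor
  vals <- em * NA_real_
  if (any(mask)) vals[mask, ] <- theta * em[mask, , drop = FALSE] / u0[mask]
  structure(list(values = if (is.vector(emission)) drop(vals) else vals,
                 mask = mask, u0 = u0, theta = theta, floor = floor),
            class = "fmt_born")
}

#' Full measurement schedule of the tomographic protocol
#'
#' Cartesian product of views, sliding patterns and detectors in a fixed
#' deterministic order (view-major, then pattern, then detector fastest).
#' The default protocol (12 patterns, 4 views, 156 detectors) yields 7488
#' source-detector combinations.
#'
#' @param n_patterns,n_views,n_detectors axis sizes (all >= 1)
#' @return data.frame with columns `view`, `pattern`, `detector`
#' @export
build_measurement_schedule <- function(n_patterns = 12, n_views = 4,
                                       n_detectors = 156) {
  if (min(n_patterns, n_views, n_detectors) < 1)
    stop("all schedule counts must be at least 1")
  data.frame(
    view = rep(seq_len(n_views), each = n_patterns * n_detectors),
    pattern = rep(rep(seq_len(n_patterns), each = n_detectors), n_views),
    detector = rep(seq_len(n_detectors), n_patterns * n_views)
  )
}
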