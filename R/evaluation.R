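# Reconstruction scoring: 50% isovolume, centroid localization error,
# reconstructed volume, and relative quantification error.

#' Isovolume mask at a fraction of the maximum
#'
#' Voxels whose value reaches `fraction * max(volume)` (the 50% isovolume by
#' default).
#'
#' @param volume numeric array (or vector) with a positive maximum
#' @param fraction threshold fraction of the maximum, in (0, 1]
#' @return logical mask, same shape
#' @export
isovolume_mask <- function(volume, fraction = 0.5) {
  m <- max(volume)
  if (!is.finite(m) || m <= 0)
    stop("no object: volume has no positive maximum")
  volume >= fraction * m
}

#' Centroid of a voxel mask (or intensity-weighted volume), mm
#'
#' Unweighted mean of voxel-center coordinates over the mask (the centroid
#' of the region); set `weights` for an intensity-weighted centroid.
#'
#' @param mask logical 3-D array (nonempty)
#' @param voxel_mm isotropic voxel size, mm
#' @param weights optional non-negative array of weights over the mask
#' @return numeric (x, y, z) centroid, mm, grid-centered world frame
#' @export
centroid <- function(mask, voxel_mm, weights = NULL) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  w <- if (is.null(weights)) rep(1, length(idx)) else {
    wv <- weights[idx]
    if (sum(wv) <= 0) stop("weights sum to zero on the mask")
    wv
  }
  ai <- arrayInd(idx, d)
  vapply(1:3, function(a) {
    sum((ai[, a] - (d[a] + 1) / 2) * voxel_mm * w) / sum(w)
  }, numeric(1))
}

#' Euclidean localization error between two centroids, mm
#' @param recon_centroid,true_centroid (x, y, z) positions, mm, same frame
#' @return distance in mm
#' @export
localization_error <- function(recon_centroid, true_centroid) {
  sqrt(sum((recon_centroid - true_centroid)^2))
}

#' Volume of a voxel mask, mm^3
#' @param mask logical array (nonempty)
#' @param voxel_mm isotropic voxel size, mm
#' @return volume in mm^3
#' @export
reconstructed_volume <- function(mask, voxel_mm) {
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  n * voxel_mm^3
}

#' Quantification of a reconstruction against the true yield
#'
#' Observed value: sum of the reconstructed yield over the reconstruction's
#' isovolume (fraction of the reconstruction maximum). Expected value: sum of
#' the true yield. Relative error:
#' `|Observed - Expected| / Expected * 100`.
#'
#' @param recon reconstructed yield array
#' @param truth true yield array
#' @param fraction isovolume threshold fraction
#' @param statistic "sum" (recovered total, default) or "mean"
#' @return list `quantification_percent`, `relative_error_percent`,
#'   `observed`, `expected`
#' @export
quantification <- function(recon, truth, fraction = 0.5,
                           statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  expected <- if (statistic == "sum") sum(truth) else
    mean(truth[truth > 0])
  if (expected == 0) stop("expected yield is zero")
  mask <- isovolume_mask(recon, fraction)
  observed <- if (statistic == "sum") sum(recon[mask]) else
    mean(recon[mask])
  list(quantification_percent = observed / expected * 100,
       relative_error_percent = abs(observed - expected) / expected * 100,
       observed = observed, expected = expected)
}

#' Score one reconstruction against the phantom truth
#'
#' Computes the three study metrics on the 50% isovolume: centroid
#' localization error (mm), reconstructed volume (mm^3), and quantification
#' (percent, with its relative error).
#'
#' @param recon_volume reconstructed yield array, spine frame
#' @param phantom the spine-frame `fmt_phantom` holding the true yield
#' @param fraction isovolume threshold fraction (default 0.5)
#' @return one-row data.frame of metrics
#' @export
evaluate_reconstruction <- function(recon_volume, phantom, fraction = 0.5) {
  v <- phantom$voxel_mm
  mask <- isovolume_mask(recon_volume, fraction)
  cen <- centroid(mask, v)
  tru <- inclusion_centroid(phantom)
  q <- quantification(recon_volume, phantom$eta, fraction)
  data.frame(localization_error_mm = localization_error(cen, tru),
             volume_mm3 = reconstructed_volume(mask, v),
             quantification_percent = q$quantification_percent,
             relative_error_percent = q$relative_error_percent,
             observed = q$observed, expected = q$expected,
             isovolume_fraction = fraction)
}
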