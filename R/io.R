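# File interfaces: NIfTI volumes with JSON sidecars, YAML study configs,
# and RDS containers for time-resolved data sets.

#' Save a phantom as NIfTI volumes with a JSON sidecar
#'
#' Writes `<path>_labels.nii.gz` and `<path>_eta.nii.gz` plus `<path>.json`
#' holding optical properties, lifetime, voxel size, geometry and axes
#' convention (Z along the spinal cord / rotation axis).
#'
#' @param phantom an `fmt_phantom`
#' @param path output path prefix
#' @return invisibly, the file names written
#' @export
save_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "fmt_phantom"))
  v <- phantom$voxel_mm
  f_lab <- paste0(path, "_labels.nii.gz")
  f_eta <- paste0(path, "_eta.nii.gz")
  f_json <- paste0(path, ".json")
  RNifti::writeNifti(RNifti::asNifti(phantom$labels,
                                     pixdim = c(v, v, v)), f_lab)
  RNifti::writeNifti(RNifti::asNifti(phantom$eta, pixdim = c(v, v, v)),
                     f_eta)
  side <- list(
    voxel_mm = v, tau_ns = phantom$tau_ns,
    properties = lapply(phantom$properties, unclass),
    geometry = phantom$geometry, view = phantom$view,
    axes = "XYZ fixed to the spine; Z along the spinal cord (rotation axis)")
  jsonlite::write_json(side, f_json, auto_unbox = TRUE, digits = NA)
  invisible(c(labels = f_lab, eta = f_eta, sidecar = f_json))
}

#' Load a phantom saved by [save_phantom()]
#' @param path the path prefix used when saving
#' @return an `fmt_phantom`
#' @export
load_phantom <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab_img <- RNifti::readNifti(paste0(path, "_labels.nii.gz"))
  eta_img <- RNifti::readNifti(paste0(path, "_eta.nii.gz"))
  props <- lapply(side$properties, function(p)
    optical_properties(p$mu_a, p$mu_s, p$g, p$n))
  structure(list(
    labels = array(as.integer(lab_img), dim = dim(lab_img)),
    eta = array(as.numeric(eta_img), dim = dim(eta_img)),
    tau_ns = side$tau_ns, voxel_mm = side$voxel_mm,
    properties = props[names(fmt_labels)],
    geometry = as.list(side$geometry),
    view = as.list(side$view)
  ), class = "fmt_phantom")
}

#' Save a reconstruction as NIfTI + JSON sidecar (spine frame)
#' @param recon an `fmt_recon`
#' @param phantom the spine-frame phantom defining the grid
#' @param path output path prefix
#' @param tag free-form configuration tag stored in the sidecar
#' @return invisibly, the file names written
#' @export
save_reconstruction <- function(recon, phantom, path, tag = "") {
  vol <- recon_to_volume(recon$eta_hat, phantom)
  v <- phantom$voxel_mm
  f_nii <- paste0(path, ".nii.gz")
  f_json <- paste0(path, ".json")
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(v, v, v)), f_nii)
  jsonlite::write_json(list(tag = tag, iterations = recon$iterations,
                            resnorm = recon$resnorm,
                            data_type = recon$data_type),
                       f_json, auto_unbox = TRUE, digits = NA)
  invisible(c(volume = f_nii, sidecar = f_json))
}

#' Read a study configuration from YAML (or JSON)
#'
#' Recognized keys mirror the arguments of [study_config()]; geometry keys
#' may be nested under `geometry` (diameter_mm, length_mm,
#' disc_thickness_mm, cord_diameter_mm) and the inclusion under `inclusion`
#' (center_mm, edge_mm, yield, tau_ns).
#'
#' @param file path to a YAML or JSON configuration file
#' @return an [study_config()]
#' @export
read_study_config <- function(file) {
  raw <- if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  args <- list()
  direct <- intersect(names(raw), names(formals(study_config)))
  args[direct] <- raw[direct]
  if (!is.null(raw$geometry)) args$phantom <- as.list(raw$geometry)
  if (!is.null(raw$inclusion)) {
    inc <- as.list(raw$inclusion)
    inc$center_mm <- as.numeric(inc$center_mm)
    args$inclusion <- inc
  }
  do.call(study_config, args)
}

#' Save / load time-resolved data containers
#'
#' TPSF sets, fluence maps and assembled data live in an RDS container with
#' axis metadata (native bin width, measurement index tables).
#'
#' @param x list-like object (e.g. the result of [simulate_excitation()])
#' @param file output `.rds` path
#' @return `save_tpsf`: invisibly, the file name; `load_tpsf`: the object
#' @export
save_tpsf <- function(x, file) {
  saveRDS(x, file)
  invisible(file)
}

#' @rdname save_tpsf
#' @export
load_tpsf <- function(file) readRDS(file)

#' Export a measurement schedule as CSV
#'
#' Adds the world-frame detector patch coordinates (x on the exit plane is
#' geometry-dependent and left NA when no phantom is given).
#'
#' @param schedule data.frame from [build_measurement_schedule()]
#' @param file output CSV path
#' @param detectors an [detector_grid()] supplying patch centers
#' @return invisibly, the file name
#' @export
write_schedule_csv <- function(schedule, file, detectors = detector_grid()) {
  jy <- (schedule$detector - 1) %% detectors$ny + 1
  jz <- (schedule$detector - 1) %/% detectors$ny + 1
  out <- cbind(schedule, x = NA_real_,
               y = detectors$y_centers[jy], z = detectors$z_centers[jz])
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}
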