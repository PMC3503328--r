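# Full in silico study: {CW, TG} x {homogeneous, heterogeneous Jacobian} x
# {single views 1-4, combined}, with seeded determinism and report output.

#' Study configuration
#'
#' Desk-scale defaults: 1 mm voxels, 1e5 photons per pattern, 2e5 per adjoint
#' super-patch (4 x 4 detector grouping), 300 ps gates at 40 ps intervals
#' over 4.8 ns, 100 solver iterations, noiseless data. Synthetic measurements
#' are always generated from the heterogeneous optical model; only the
#' Jacobian model varies. Data and Jacobian Green's functions use independent
#' seed streams unless `independent_seeds = FALSE` (consistency testing).
#'
#' @param seed base integer seed; every stochastic stage derives its own
#' @param voxel_mm phantom voxel size, mm
#' @param phantom named list of [build_spine_phantom()] geometry overrides
#' @param inclusion named list: `center_mm`, `edge_mm`, `yield`, `tau_ns`
#' @param n_views,n_patterns acquisition protocol size
#' @param pattern_width_mm transverse pattern extent, mm
#' @param detectors named list: `ny`, `nz`, `pitch_mm`
#' @param superpatch detectors per adjoint group, c(y, z)
#' @param n_photons_pattern,n_photons_adjoint photon budgets
#' @param nt,dt_ns native time axis (bins, ns)
#' @param gates named list: `width_ps`, `step_ps`, `window_ps`
#' @param early_threshold,late_threshold gate-selection fractions of the peak
#' @param max_early_gates cap on early gates kept per measurement (evenly
#'   subsampled from the rising set; memory control)
#' @param iterations CGLS iterations per stage
#' @param column_scaling diagonal sensitivity normalization in the solver
#'   (see [solve_least_squares()])
#' @param theta Born system constant
#' @param noise NULL (noiseless) or list(scale =, ...) for Poisson noise
#' @param independent_seeds use Jacobian seeds independent of data seeds
#' @param isovolume_fraction evaluation threshold fraction
#' @return object of class `fmt_study_config`
#' @export
study_config <- function(seed = 1, voxel_mm = 1.0, phantom = list(),
                         inclusion = list(center_mm = c(4, 0, 0),
                                          edge_mm = 3, yield = 0.1,
                                          tau_ns = 0.5),
                         n_views = 4, n_patterns = 12, pattern_width_mm = 10,
                         detectors = list(ny = 12, nz = 13, pitch_mm = 2.48),
                         superpatch = c(4, 4),
                         n_photons_pattern = 1e5, n_photons_adjoint = 2e5,
                         nt = 128, dt_ns = 0.04,
                         gates = list(width_ps = 300, step_ps = 40,
                                      window_ps = 4800),
                         early_threshold = 0.25, late_threshold = 0.5,
                         max_early_gates = 3, iterations = 100,
                         column_scaling = FALSE, theta = 1,
                         noise = NULL, independent_seeds = TRUE,
                         isovolume_fraction = 0.5) {
  cfg <- as.list(environment())
  class(cfg) <- "fmt_study_config"
  cfg
}

# spine-frame row ordering of a laboratory-frame fluence matrix:
# G_spine = G_lab[reindex, ]
.view_reindex <- function(phantom, k_quarters, spine_tidx, lab_tidx) {
  perm <- .rot90_perm(dim(phantom$labels), k_quarters)
  match(perm[spine_tidx], lab_tidx)
}

# evenly subsample a gate set to at most `cap` entries (keep ends)
.cap_gates <- function(gates, cap) {
  if (length(gates) <= cap) return(gates)
  gates[unique(round(seq(1, length(gates), length.out = cap)))]
}

# Monte Carlo sweep of one view: excitation scan + adjoint patches, rows
# reordered into the fixed spine frame.
.mc_view <- function(ph_lab, cfg, detg, sp, seed_x, seed_m, reindex) {
  exc <- simulate_excitation(ph_lab, cfg$n_photons_pattern, seed_x,
                             detectors = detg, n_patterns = cfg$n_patterns,
                             pattern_width_mm = cfg$pattern_width_mm,
                             nt = cfg$nt, dt_ns = cfg$dt_ns)
  gx <- lapply(exc$fluence, function(g) g[reindex, , drop = FALSE])
  gm <- lapply(seq_len(sp$n_patches), function(s) {
    adjoint_emission_greens(ph_lab, sp$patches[[s]], cfg$n_photons_adjoint,
                            derive_seed(seed_m, 202L, s), nt = cfg$nt,
                            dt_ns = cfg$dt_ns)[reindex, , drop = FALSE]
  })
  list(gx = gx, gm = gm, u0 = cw_from_tpsf(exc$tpsf))
}

#' Run the full in silico study grid
#'
#' Simulates the tomographic data once on the heterogeneous phantom, builds
#' both Jacobian models with independent Monte Carlo seeds, reconstructs all
#' 2 (data types) x 2 (optical models) x (n_views + combined) configurations,
#' and scores each against the true inclusion.
#'
#' @param config an [study_config()]
#' @param verbose print stage progress?
#' @return object of class `fmt_report`: data.frame with one row per
#'   configuration (model, data_type, views, localization error, 50%
#'   isovolume, quantification), with the phantom, per-configuration volumes
#'   and the configuration attached as attributes
#' @export
run_study <- function(config = study_config(), verbose = interactive()) {
  stopifnot(inherits(config, "fmt_study_config"))
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## ---- phantom ----
  phantom <- stage("phantom", {
    ph <- do.call(build_spine_phantom,
                  c(list(voxel_mm = cfg$voxel_mm), cfg$phantom))
    place_inclusion(ph, center_mm = cfg$inclusion$center_mm,
                    edge_mm = cfg$inclusion$edge_mm,
                    yield_value = cfg$inclusion$yield,
                    tau_ns = cfg$inclusion$tau_ns)
  })
  spine_tidx <- tissue_indices(phantom)
  ncols <- length(spine_tidx)
  eta_spine <- phantom$eta[spine_tidx]
  detg <- detector_grid(cfg$detectors$ny, cfg$detectors$nz,
                        cfg$detectors$pitch_mm)
  sp <- superpatch_layout(detg, cfg$superpatch[1], cfg$superpatch[2])
  ndet <- detg$ny * detg$nz
  nmeas <- cfg$n_patterns * ndet
  gates <- make_gate_schedule(cfg$gates$width_ps, cfg$gates$step_ps,
                              cfg$gates$window_ps)
  bin_ps <- cfg$dt_ns * 1000
  step_bins <- gates$step_ps / bin_ps
  wbins <- as.integer(ceiling(gates$width_ps / bin_ps))
  views <- seq_len(cfg$n_views)
  reindex <- lapply(views, function(v) {
    ph_v <- apply_view(phantom, view_transform(v))
    .view_reindex(phantom, v - 1L, spine_tidx, tissue_indices(ph_v))
  })

  ## ---- synthetic data (always heterogeneous) ----
  data_v <- vector("list", cfg$n_views)
  for (v in views) {
    say("data: view %d (heterogeneous forward model)", v)
    stage(sprintf("data view %d", v), {
      ph_v <- apply_view(phantom, view_transform(v))
      mv <- .mc_view(ph_v, cfg, detg, sp, derive_seed(cfg$seed, 11L, v),
                     derive_seed(cfg$seed, 12L, v), reindex[[v]])
      em <- simulate_emission(eta_spine, phantom$tau_ns, mv$gx, mv$gm,
                              sp$of_detector, cfg$voxel_mm, cfg$dt_ns)
      u0 <- mv$u0
      if (!is.null(cfg$noise)) {
        em <- add_poisson_noise(em, cfg$noise$scale,
                                derive_seed(cfg$seed, 13L, v))
        u0 <- add_poisson_noise(u0, cfg$noise$scale,
                                derive_seed(cfg$seed, 14L, v))
      }
      gated <- apply_gates(em, gates, bin_ps)
      born_cw <- born_normalize(cw_from_tpsf(em), u0, cfg$theta)
      born_tg <- born_normalize(gated, u0, cfg$theta,
                                floor = born_cw$floor)
      early <- vector("list", nmeas)
      late <- integer(nmeas)
      early_ok <- logical(nmeas)
      late_ok <- logical(nmeas)
      for (m in seq_len(nmeas)) {
        if (!born_cw$mask[m]) next
        se <- select_early_gates(gated[m, ], cfg$early_threshold)
        sl <- select_late_gate(gated[m, ], cfg$late_threshold)
        early[[m]] <- .cap_gates(se$gates, cfg$max_early_gates)
        early_ok[m] <- se$valid
        late[m] <- if (sl$valid) sl$gate else NA_integer_
        late_ok[m] <- sl$valid
      }
      data_v[[v]] <- list(u0 = u0, mask = born_cw$mask,
                          born_cw = born_cw$values, born_tg = born_tg$values,
                          early = early, early_ok = early_ok,
                          late = late, late_ok = late_ok)
    })
  }

  ## ---- per-model assembly and reconstruction ----
  view_settings <- c(as.list(views), list(views))
  names(view_settings) <- c(as.character(views), "comb")
  report <- list()
  volumes <- list()

  for (model in c("heterogeneous", "homogeneous")) {
    ph_model <- if (model == "homogeneous") homogenize(phantom) else phantom
    seed_code <- if (model == "homogeneous") 31L else 21L
    blocks <- list(cw = vector("list", cfg$n_views),
                   early = vector("list", cfg$n_views),
                   late = vector("list", cfg$n_views))
    ydat <- list(cw = vector("list", cfg$n_views),
                 early = vector("list", cfg$n_views),
                 late = vector("list", cfg$n_views))

    for (v in views) {
      say("jacobian: view %d (%s model)", v, model)
      stage(sprintf("jacobian view %d (%s)", v, model), {
        dv <- data_v[[v]]
        ph_v <- apply_view(ph_model, view_transform(v))
        sx <- if (cfg$independent_seeds) derive_seed(cfg$seed, seed_code, v)
              else derive_seed(cfg$seed, 11L, v)
        sm <- if (cfg$independent_seeds)
                derive_seed(cfg$seed, seed_code + 1L, v)
              else derive_seed(cfg$seed, 12L, v)
        mv <- .mc_view(ph_v, cfg, detg, sp, sx, sm, reindex[[v]])

        # CW rows
        mask_cw <- dv$mask & is.finite(dv$born_cw) & is.finite(mv$u0) & mv$u0 > 0
        ncw <- sum(mask_cw)
        bl <- .jblock_create_cpp(ncw, ncols)
        rows <- build_jacobian(mv$gx, mv$gm, dv$u0, sp$of_detector,
                               phantom$tau_ns, cfg$voxel_mm, "cw",
                               mask = mask_cw, theta = cfg$theta,
                               dt_ns = cfg$dt_ns, block = bl)$rows
        blocks$cw[[v]] <- bl
        ydat$cw[[v]] <- dv$born_cw[rows$measurement]

        # early-gate rows
        mask_e <- dv$mask & dv$early_ok & is.finite(mv$u0) & mv$u0 > 0
        starts_e <- lapply(seq_len(nmeas), function(m)
          if (mask_e[m]) as.integer((dv$early[[m]] - 1L) * step_bins)
          else integer(0))
        ne <- sum(lengths(starts_e))
        if (ne > 0) {
          bl <- .jblock_create_cpp(ne, ncols)
          rows <- build_jacobian(mv$gx, mv$gm, dv$u0, sp$of_detector,
                                 phantom$tau_ns, cfg$voxel_mm, "tg",
                                 gate_starts = starts_e,
                                 gate_width_bins = wbins, mask = mask_e,
                                 theta = cfg$theta, dt_ns = cfg$dt_ns,
                                 block = bl)$rows
          blocks$early[[v]] <- bl
          ydat$early[[v]] <- dv$born_tg[cbind(rows$measurement,
                                              rows$gate_start_bin / step_bins + 1L)]
        }

        # late-gate rows
        mask_l <- dv$mask & dv$late_ok & is.finite(mv$u0) & mv$u0 > 0
        starts_l <- lapply(seq_len(nmeas), function(m)
          if (mask_l[m]) as.integer((dv$late[m] - 1L) * step_bins)
          else integer(0))
        nl <- sum(lengths(starts_l))
        bl <- .jblock_create_cpp(nl, ncols)
        rows <- build_jacobian(mv$gx, mv$gm, dv$u0, sp$of_detector,
                               phantom$tau_ns, cfg$voxel_mm, "tg",
                               gate_starts = starts_l,
                               gate_width_bins = wbins, mask = mask_l,
                               theta = cfg$theta, dt_ns = cfg$dt_ns,
                               block = bl)$rows
        blocks$late[[v]] <- bl
        ydat$late[[v]] <- dv$born_tg[cbind(rows$measurement,
                                           rows$gate_start_bin / step_bins + 1L)]
        rm(mv); gc(FALSE)
      })
    }

    sys <- lapply(c(cw = "cw", early = "early", late = "late"), function(k) {
      has <- which(!vapply(blocks[[k]], is.null, logical(1)))
      combine_views(blocks[[k]][has], ydat[[k]][has], views = has)
    })

    for (vs_name in names(view_settings)) {
      vs <- view_settings[[vs_name]]
      for (dtype in c("cw", "tg")) {
        tag <- sprintf("%s_%s_%s", substr(model, 1, 4), dtype, vs_name)
        say("reconstruct: %s", tag)
        row <- tryCatch({
          rec <- if (dtype == "cw") {
            reconstruct_cw(subset_views(sys$cw, vs),
                           iterations = cfg$iterations,
                           column_scaling = cfg$column_scaling)
          } else {
            reconstruct_tg(subset_views(sys$early, vs), NULL,
                           subset_views(sys$late, vs), NULL,
                           iterations = cfg$iterations,
                           column_scaling = cfg$column_scaling)
          }
          vol <- recon_to_volume(rec$eta_hat, phantom)
          volumes[[tag]] <- vol
          met <- evaluate_reconstruction(vol, phantom,
                                         cfg$isovolume_fraction)
          cbind(data.frame(model = model, data_type = toupper(dtype),
                           views = vs_name, status = "ok"), met)
        }, error = function(e) {
          data.frame(model = model, data_type = toupper(dtype),
                     views = vs_name,
                     status = paste("failed:", conditionMessage(e)),
                     localization_error_mm = NA_real_, volume_mm3 = NA_real_,
                     quantification_percent = NA_real_,
                     relative_error_percent = NA_real_, observed = NA_real_,
                     expected = NA_real_,
                     isovolume_fraction = cfg$isovolume_fraction)
        })
        report[[tag]] <- row
      }
    }
    rm(blocks, ydat, sys); gc(FALSE)
  }

  out <- do.call(rbind, report)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  attr(out, "phantom") <- phantom
  attr(out, "volumes") <- volumes
  attr(out, "true_centroid") <- inclusion_centroid(phantom)
  class(out) <- c("fmt_report", "data.frame")
  out
}

#' Write a study report to CSV and JSON
#'
#' The CSV stores doubles at full precision (round-trips exactly through
#' [utils::read.csv()]); the JSON carries the numbers plus seed and budget
#' metadata.
#'
#' @param report an `fmt_report` from [run_study()]
#' @param path output path prefix (writes `<path>.csv` and `<path>.json`)
#' @return invisibly, the written file names
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  ok <- tryCatch({
    write.csv(fmt, csv, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) stop("unwritable path: ", csv, call. = FALSE))
  cfg <- attr(report, "config")
  meta <- list(
    seed = cfg$seed,
    n_photons_pattern = cfg$n_photons_pattern,
    n_photons_adjoint = cfg$n_photons_adjoint,
    voxel_mm = cfg$voxel_mm,
    iterations = cfg$iterations,
    package_version = as.character(utils::packageVersion("spinefmt")),
    rows = nrow(df),
    failed_rows = sum(df$status != "ok")
  )
  jsonlite::write_json(list(report = df, meta = meta), json,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Read back a report CSV written by [write_report()]
#' @param csv path to the CSV file
#' @return data.frame with numeric columns restored
#' @export
read_report <- function(csv) {
  df <- read.csv(csv, stringsAsFactors = FALSE)
  numcols <- c("localization_error_mm", "volume_mm3",
               "quantification_percent", "relative_error_percent",
               "observed", "expected", "isovolume_fraction")
  for (j in intersect(numcols, names(df))) df[[j]] <- as.numeric(df[[j]])
  df
}
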