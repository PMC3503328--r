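test_that("homogenize assigns bone properties everywhere, idempotently", {
  ph <- small_phantom()
  h <- homogenize(ph)
  expect_equal(h$properties$DISC$mu_a, 0.04)
  expect_equal(h$properties$DISC$mu_s, 12)
  expect_equal(h$properties$SPINAL_CORD$mu_a, 0.04)
  # geometry and labels untouched
  expect_identical(h$labels, ph$labels)
  expect_identical(homogenize(h)$properties, h$properties)
})

test_that("Born-normalized data equal J eta exactly for shared Green's
           functions (CW and gated)", {
  g <- small_greens()
  em <- simulate_emission(g$eta, 0.5, g$exc$fluence, g$gm,
                          g$sp$of_detector, 1)
  sched <- make_gate_schedule(300, 40, 96 * 40)
  gated <- apply_gates(em, sched)
  nmeas <- nrow(em)
  m_sel <- c(which.max(g$u0), which(g$u0 > 0)[5])
  mask <- seq_len(nmeas) %in% m_sel
  # time-gated rows at a few gates
  starts <- rep(list(integer(0)), nmeas)
  for (m in m_sel) starts[[m]] <- c(4L, 9L, 20L)
  jb <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector, 0.5, 1,
                       "tg", gate_starts = starts, gate_width_bins = 8,
                       mask = mask)
  expect_true(all(jb$J >= 0))
  pred <- as.vector(jb$J %*% g$eta)
  obs <- mapply(function(m, s) gated[m, s + 1] / g$u0[m],
                jb$rows$measurement, jb$rows$gate_start_bin)
  expect_equal(pred, obs, tolerance = 1e-12)
  # CW rows against the time-integrated data
  jcw <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector, 0.5, 1,
                        "cw", mask = mask)
  expect_equal(as.vector(jcw$J %*% g$eta),
               cw_from_tpsf(em)[jcw$rows$measurement] /
                 g$u0[jcw$rows$measurement],
               tolerance = 1e-12)
})

test_that("a CW row equals the sum of an exact gate tiling of TG rows", {
  g <- small_greens()
  nmeas <- g$n_patterns * g$detg$ny * g$detg$nz
  m <- which.max(g$u0)
  mask <- seq_len(nmeas) == m
  starts <- rep(list(integer(0)), nmeas)
  starts[[m]] <- 0:(g$nt - 1) # width = step = one bin: exact tiling
  jt <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector, 0.5, 1,
                       "tg", gate_starts = starts, gate_width_bins = 1,
                       mask = mask)
  jc <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector, 0.5, 1,
                       "cw", mask = mask)
  expect_equal(colSums(jt$J), as.vector(jc$J), tolerance = 1e-12)
})

test_that("adjoint-assembled entries match finite-difference perturbation", {
  g <- small_greens()
  nmeas <- g$n_patterns * g$detg$ny * g$detg$nz
  m <- which.max(g$u0)
  mask <- seq_len(nmeas) == m
  # voxel near the inclusion (well-sampled sensitivity)
  vox <- which(g$eta > 0)[1]
  jcw <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector, 0.5, 1,
                        "cw", mask = mask)
  fd1 <- finite_difference_jacobian(g$exc$fluence, g$gm, g$sp$of_detector,
                                    g$u0, 0.5, 1, m, vox, delta_eta = 0.05,
                                    data_type = "cw")
  fd2 <- finite_difference_jacobian(g$exc$fluence, g$gm, g$sp$of_detector,
                                    g$u0, 0.5, 1, m, vox, delta_eta = 0.8,
                                    data_type = "cw")
  # the emission model is linear in eta: independent of delta, equal to J
  expect_equal(fd1, fd2, tolerance = 1e-9)
  expect_equal(fd1, jcw$J[1, vox], tolerance = 1e-9)
  # gated entry
  starts <- rep(list(integer(0)), nmeas); starts[[m]] <- 6L
  jtg <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector, 0.5, 1,
                        "tg", gate_starts = starts, gate_width_bins = 8,
                        mask = mask)
  fdg <- finite_difference_jacobian(g$exc$fluence, g$gm, g$sp$of_detector,
                                    g$u0, 0.5, 1, m, vox, delta_eta = 0.1,
                                    data_type = "tg", gate_start_bin = 6L,
                                    gate_width_bins = 8)
  expect_equal(fdg, jtg$J[1, vox], tolerance = 1e-9)
})

test_that("Jacobian column predicts independently simulated data within
           Monte Carlo bounds", {
  # data Green's functions and Jacobian Green's functions from disjoint
  # seeds; agreement limited only by MC noise (3 sigma over repeats)
  g <- small_greens()
  nmeas <- g$n_patterns * g$detg$ny * g$detg$nz
  m <- which.max(g$u0)
  mask <- seq_len(nmeas) == m
  # predictions J eta from 3 independent Green's realizations
  preds <- vapply(c(11L, 301L, 302L), function(s) {
    gk <- small_greens(seed = s)
    jk <- build_jacobian(gk$exc$fluence, gk$gm, gk$u0, gk$sp$of_detector,
                         0.5, 1, "cw", mask = mask)
    as.vector(jk$J %*% gk$eta)
  }, numeric(1))
  # directly simulated Born data from 4 further independent realizations
  reps <- vapply(1:4, function(k) {
    gk <- small_greens(seed = 500 + k)
    (cw_from_tpsf(simulate_emission(gk$eta, 0.5, gk$exc$fluence, gk$gm,
                                    gk$sp$of_detector, 1))[m]) / gk$u0[m]
  }, numeric(1))
  se <- sqrt(var(reps) / length(reps) + var(preds) / length(preds))
  expect_lt(abs(mean(reps) - mean(preds)), 3 * se)
})

test_that("homogeneous and heterogeneous Jacobians differ", {
  g <- small_greens()
  hph <- homogenize(g$ph)
  exc_h <- simulate_excitation(hph, 3e4, 11, detectors = g$detg,
                               n_patterns = g$n_patterns,
                               pattern_width_mm = 6, nt = 96)
  gm_h <- lapply(seq_len(g$sp$n_patches), function(s)
    adjoint_emission_greens(hph, g$sp$patches[[s]], 3e4,
                            derive_seed(11, 7L, s), nt = 96))
  nmeas <- g$n_patterns * g$detg$ny * g$detg$nz
  m <- which.max(g$u0)
  mask <- seq_len(nmeas) == m
  jhet <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector,
                         0.5, 1, "cw", mask = mask)$J
  jhom <- build_jacobian(exc_h$fluence, gm_h, g$u0, g$sp$of_detector,
                         0.5, 1, "cw", mask = mask)$J
  # normalized difference is clearly nonzero
  dif <- sum(abs(jhet / max(jhet) - jhom / max(jhom)))
  expect_gt(dif, 1)
})

test_that("empty gate set and mismatched axes are rejected", {
  g <- small_greens()
  expect_error(build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector,
                              0.5, 1, "tg"), "gate")
  short <- lapply(g$gm, function(x) x[, 1:10])
  expect_error(build_jacobian(g$exc$fluence, short, g$u0, g$sp$of_detector,
                              0.5, 1, "cw"), "mismatch")
})
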