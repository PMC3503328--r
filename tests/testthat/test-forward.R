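test_that("analytic diffusion TPSF has the closed-form structure", {
  mu_a <- 0.004; mu_sp <- 1.2; n <- 1.37; v <- 299.792458 / n
  t <- c(0.1, 0.5, 1, 2)
  # decay limit
  expect_equal(analytic_tpsf(mu_a, mu_sp, n, 5, 1e4), 0)
  # doubling mu_a multiplies by exp(-dmu * v * t) at fixed t (D changes too,
  # so compare with the same transport coefficient held fixed)
  f1 <- analytic_tpsf(mu_a, mu_sp, n, 5, t)
  f2 <- analytic_tpsf(2 * mu_a, mu_sp - mu_a, n, 5, t) # same mu_a + mu_sp' sum
  expect_equal(f2 / f1, exp(-mu_a * v * t), tolerance = 1e-12)
  # spatial normalization: 4 pi int r^2 phi dr = v * exp(-mu_a v t)
  tt <- 0.5
  r <- seq(1e-3, 120, by = 1e-3)
  num <- sum(4 * pi * r^2 * analytic_tpsf(mu_a, mu_sp, n, r, tt)) * 1e-3
  expect_equal(num, v * exp(-mu_a * v * tt), tolerance = 1e-4)
  expect_error(analytic_tpsf(mu_a, mu_sp, n, 5, 0), "positive")
})

test_that("every Monte Carlo run conserves energy to 1e-6", {
  ph <- small_phantom()
  runs <- list(
    run_mc(ph, pattern_source(2, 4, 20, 6), 5e3, seed = 1,
           detectors = small_detgrid()),
    run_mc(ph, point_source(c(0, 0, 0)), 5e3, seed = 2),
    run_mc(homogenize(ph), adjoint_source(c(-3, 3), c(-4, 4)), 5e3, seed = 3))
  for (mc in runs) {
    tal <- mc$tallies
    bal <- tal[["absorbed"]] + tal[["exited"]] + tal[["cutoff"]] +
      tal[["roulette_net"]]
    expect_lt(abs(bal - tal[["launched"]]), 1e-6)
    expect_true(all(mc$fluence >= 0))
    expect_lte(tal[["detected"]], tal[["exited"]] + 1e-12)
  }
})

test_that("fluence is causal: nothing arrives faster than c/n", {
  ph <- small_phantom(with_inclusion = FALSE)
  mc <- run_mc(ph, point_source(c(0, 0, 0)), 2e4, seed = 5)
  d <- dim(ph$labels)
  co <- voxel_coordinates(ph)
  ai <- arrayInd(mc$tissue_idx, d)
  r <- sqrt(co$x[ai[, 1]]^2 + co$y[ai[, 2]]^2 + co$z[ai[, 3]]^2)
  sel <- which(r >= 8)
  v_tis <- 299.792458 / 1.37
  for (i in sel[seq(1, length(sel), by = 37)]) {
    nz <- which(mc$fluence[i, ] > 0)
    if (length(nz) == 0) next
    # segment binning uses midpoints, allow one bin of slack
    expect_gte(nz[1], floor((r[i] / v_tis) / 0.04) - 1)
  }
})

test_that("MC matches the analytic diffusion Green's function in a
           homogeneous medium", {
  # all-bone block, interior point source, fluence shell at r = 5 mm
  ph <- build_spine_phantom(voxel_mm = 1, diameter_mm = 48, length_mm = 50,
                            disc_thickness_mm = 4, margin_mm = 1)
  ph$labels[ph$labels > 0] <- fmt_labels[["BONE"]]
  nt <- 32
  mc <- run_mc(ph, point_source(c(0, 0, 0)), 3e5, seed = 99, nt = nt)
  d <- dim(ph$labels)
  co <- voxel_coordinates(ph)
  ai <- arrayInd(mc$tissue_idx, d)
  r <- sqrt(co$x[ai[, 1]]^2 + co$y[ai[, 2]]^2 + co$z[ai[, 3]]^2)
  shell <- which(abs(r - 5) < 0.2)
  f_mc <- colMeans(mc$fluence[shell, ])
  se <- apply(mc$fluence[shell, ], 2, sd) / sqrt(length(shell))
  tb <- (seq_len(nt) - 0.5) * 0.04
  f_th <- analytic_tpsf(0.004, 1.2, 1.37, 5, tb) * 0.04
  ok <- f_mc > 0 & se / f_mc < 0.05
  expect_gte(sum(ok), 10)
  expect_lt(max(abs(f_mc[ok] - f_th[ok]) / f_th[ok]), 0.15)
})

test_that("MC is deterministic per seed", {
  ph <- small_phantom()
  a <- run_mc(ph, pattern_source(2, 4, 20, 6), 5e3, seed = 42,
              detectors = small_detgrid())
  b <- run_mc(ph, pattern_source(2, 4, 20, 6), 5e3, seed = 42,
              detectors = small_detgrid())
  c <- run_mc(ph, pattern_source(2, 4, 20, 6), 5e3, seed = 43,
              detectors = small_detgrid())
  expect_identical(a$det_tpsf, b$det_tpsf)
  expect_identical(a$fluence, b$fluence)
  expect_false(identical(a$det_tpsf, c$det_tpsf))
})

test_that("illumination over background-only area detects nothing", {
  ph <- small_phantom(with_inclusion = FALSE)
  # rectangle in the air corner of the entry face (outside the cylinder)
  src <- structure(list(type = "rect", side = "xmin",
                        y0 = 7.5, y1 = 9.5, z0 = -9, z1 = 9),
                   class = "fmt_source")
  mc <- run_mc(ph, src, 5e3, seed = 4, detectors = small_detgrid())
  expect_true(all(mc$det_tpsf == 0))
})

test_that("excitation scan bookkeeping and seeding", {
  g <- small_greens()
  expect_equal(nrow(g$exc$tpsf), g$n_patterns * g$detg$ny * g$detg$nz)
  # deterministic reruns
  exc2 <- simulate_excitation(g$ph, 3e4, 11, detectors = g$detg,
                              n_patterns = g$n_patterns,
                              pattern_width_mm = 6, nt = 96)
  expect_identical(exc2$tpsf, g$exc$tpsf)
})

test_that("transmitted weight is reciprocal under source/detector swap", {
  # laterally mirrored pair on a symmetric phantom: equal within 3 sigma
  ph <- small_phantom(with_inclusion = FALSE)
  detg <- detector_grid(ny = 3, nz = 1, pitch_mm = 4) # y centers -4, 0, 4
  w12 <- w21 <- numeric(6)
  for (k in 1:6) {
    m1 <- run_mc(ph, structure(list(type = "rect", side = "xmin", y0 = 2,
                                    y1 = 6, z0 = -2, z1 = 2),
                               class = "fmt_source"),
                 3e4, seed = 100 + k, detectors = detg,
                 record_fluence = FALSE)
    w12[k] <- sum(m1$det_tpsf[1, ])   # detector at y in [-6, -2]
    m2 <- run_mc(ph, structure(list(type = "rect", side = "xmin", y0 = -6,
                                    y1 = -2, z0 = -2, z1 = 2),
                               class = "fmt_source"),
                 3e4, seed = 200 + k, detectors = detg,
                 record_fluence = FALSE)
    w21[k] <- sum(m2$det_tpsf[3, ])   # detector at y in [2, 6]
  }
  se <- sqrt(var(w12) / 6 + var(w21) / 6)
  expect_lt(abs(mean(w12) - mean(w21)), 3 * se + 1e-12)
})

test_that("adjoint Green's functions are non-negative and attenuate", {
  ph <- small_phantom(with_inclusion = FALSE)
  gm <- adjoint_emission_greens(ph, list(y_range = c(-3, 3),
                                         z_range = c(-4, 4)), 2e4, seed = 8)
  expect_true(all(gm >= 0))
  # a nearly opaque medium confines fluence to the entry side
  ph2 <- ph
  ph2$properties$BONE <- optical_properties(300, 12)
  ph2$properties$DISC <- optical_properties(300, 5)
  ph2$properties$SPINAL_CORD <- optical_properties(300, 8.9)
  gm2 <- adjoint_emission_greens(ph2, list(y_range = c(-3, 3),
                                           z_range = c(-4, 4)), 2e4, seed = 8)
  d <- dim(ph$labels)
  co <- voxel_coordinates(ph)
  ai <- arrayInd(tissue_indices(ph), d)
  deep <- which(co$x[ai[, 1]] < 2)  # more than ~4 mm from the exit face
  expect_equal(sum(gm2[deep, ]), 0, tolerance = 1e-12)
})

test_that("emission TPSFs are linear in the yield and reduce correctly", {
  g <- small_greens()
  em1 <- simulate_emission(g$eta, 0.5, g$exc$fluence, g$gm,
                           g$sp$of_detector, 1)
  # eta = 0 gives zero
  em0 <- simulate_emission(0 * g$eta, 0.5, g$exc$fluence, g$gm,
                           g$sp$of_detector, 1)
  expect_true(all(em0 == 0))
  # exact linearity
  em2 <- simulate_emission(2 * g$eta, 0.5, g$exc$fluence, g$gm,
                           g$sp$of_detector, 1)
  expect_equal(em2, 2 * em1, tolerance = 1e-12)
  # tau -> 0 limit: kernel becomes a delta; compare against a direct
  # discrete convolution for one measurement
  em_d <- simulate_emission(g$eta, 0, g$exc$fluence, g$gm,
                            g$sp$of_detector, 1)
  supp <- which(g$eta > 0)
  m <- 1L # pattern 1, detector 1
  s <- g$sp$of_detector[1]
  nt <- g$nt
  f <- numeric(nt)
  for (t1 in seq_len(nt)) {
    gx_t <- g$exc$fluence[[1]][supp, t1]
    for (t2 in seq_len(nt - t1 + 1)) {
      f[t1 + t2 - 1] <- f[t1 + t2 - 1] +
        sum(g$eta[supp] * gx_t * g$gm[[s]][supp, t2])
    }
  }
  expect_equal(em_d[m, ], f, tolerance = 1e-10)
  # mismatched axes error
  expect_error(simulate_emission(g$eta, 0.5,
                                 lapply(g$exc$fluence, function(x) x[, 1:10]),
                                 g$gm, g$sp$of_detector, 1),
               "mismatch")
})
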