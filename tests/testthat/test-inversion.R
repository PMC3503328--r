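test_that("identity system returns the data", {
  y <- c(3, 0, 2.5, 1)
  rec <- solve_least_squares(diag(4), y, iterations = 10)
  expect_equal(rec$eta_hat, y, tolerance = 1e-8)
})

test_that("consistent systems are solved to numerical residual", {
  set.seed(21)
  J <- matrix(rexp(60 * 40), 60, 40)
  eta <- numeric(40); eta[c(5, 17)] <- c(1, 0.3)
  y <- as.vector(J %*% eta)
  rec <- solve_least_squares(J, y, iterations = 100)
  expect_lt(tail(rec$resnorm, 1), 1e-6 * sqrt(sum(y^2)))
  expect_true(all(rec$eta_hat >= 0))
})

test_that("CGLS matches the base-R least-squares solution at convergence", {
  set.seed(8)
  J <- matrix(rnorm(50 * 12), 50, 12)
  y <- rnorm(50)
  rec <- solve_least_squares(J, y, iterations = 60)
  ref <- qr.solve(J, y) # overdetermined full-rank least squares
  expect_equal(rec$eta_raw, as.vector(ref), tolerance = 1e-8)
})

test_that("zero iterations return the initial guess; solver is
           degree-1 homogeneous from a zero start", {
  set.seed(3)
  J <- matrix(runif(30 * 10), 30, 10)
  y <- as.vector(J %*% runif(10))
  x0 <- runif(10)
  rec0 <- solve_least_squares(J, y, iterations = 0, initial_guess = x0)
  expect_equal(rec0$eta_raw, x0)
  r1 <- solve_least_squares(J, y, iterations = 25)
  r2 <- solve_least_squares(J, 2 * y, iterations = 25)
  expect_equal(r2$eta_hat, 2 * r1$eta_hat, tolerance = 1e-10)
  # zero data give a zero reconstruction
  expect_equal(reconstruct_cw(J, 0 * y)$eta_hat, numeric(10))
})

test_that("residual norm is non-increasing on every run", {
  set.seed(14)
  for (k in 1:5) {
    J <- matrix(rnorm(40 * 25), 40, 25)
    y <- rnorm(40) # inconsistent
    rec <- solve_least_squares(J, y, iterations = 40)
    dr <- diff(rec$resnorm)
    expect_true(all(dr <= 1e-10 * rec$resnorm[1]))
  }
})

test_that("degenerate systems are rejected", {
  expect_error(solve_least_squares(matrix(1, 2, 2), c(1, 2, 3)), "match")
  expect_error(solve_least_squares(matrix(NA_real_, 2, 2), c(1, 2)),
               "finite")
  expect_error(solve_least_squares(matrix(0, 0, 0), numeric(0)), "empty")
})

test_that("external single-precision blocks agree with the dense solver", {
  set.seed(5)
  J <- matrix(runif(80 * 30), 80, 30)
  eta <- numeric(30); eta[7] <- 2
  y <- as.vector(J %*% eta)
  dense <- solve_least_squares(J, y, iterations = 50)
  jbc <- spinefmt:::.jblock_create_cpp
  jbf <- spinefmt:::.jblock_fill_cpp
  bl1 <- jbc(50L, 30L)
  jbf(bl1, t(J[1:50, ]), 0:49, 0:49, rep(1, 50))
  bl2 <- jbc(30L, 30L)
  jbf(bl2, t(J[51:80, ]), 0:29, 0:29, rep(1, 30))
  sys <- combine_views(list(bl1, bl2), list(y[1:50], y[51:80]),
                       views = c(1, 2))
  recb <- solve_least_squares(sys, iterations = 50)
  expect_equal(recb$eta_hat, dense$eta_hat, tolerance = 1e-3)
  # single-view subset equals the dense solve on that row block
  rec1 <- solve_least_squares(subset_views(sys, 1), iterations = 50)
  dense1 <- solve_least_squares(J[1:50, ], y[1:50], iterations = 50)
  expect_equal(rec1$eta_hat, dense1$eta_hat, tolerance = 1e-3)
})

test_that("two-stage gated reconstruction seeds the late solve with the
           early result", {
  set.seed(9)
  J <- matrix(runif(40 * 15), 40, 15)
  eta <- numeric(15); eta[4] <- 1
  y <- as.vector(J %*% eta)
  # early solution already exact for the late system: stage 2 keeps it
  rec <- reconstruct_tg(J, y, J, y, iterations = 50)
  expect_equal(rec$eta_hat, solve_least_squares(J, y, 50)$eta_hat,
               tolerance = 1e-6)
  expect_lt(tail(rec$resnorm, 1), 1e-8 * sqrt(sum(y^2)) + 1e-12)
  # zero late data drive the output toward zero
  rec0 <- reconstruct_tg(J, y, J, 0 * y, iterations = 50)
  expect_lt(sum(rec0$eta_hat), 1e-6)
  # empty early system falls back to late-only with a warning
  expect_warning(recf <- reconstruct_tg(NULL, NULL, J, y, iterations = 50),
                 "early")
  expect_equal(recf$eta_hat, solve_least_squares(J, y, 50)$eta_hat)
})

test_that("combining one view reproduces the single-view system; row
           counts add", {
  set.seed(2)
  J1 <- matrix(runif(20 * 10), 20, 10)
  J2 <- matrix(runif(12 * 10), 12, 10)
  y1 <- runif(20); y2 <- runif(12)
  sys <- combine_views(list(J1, J2), list(y1, y2), views = c(1, 2))
  expect_equal(nrow(sys$J), 32)
  expect_equal(sys$J[1:20, ], J1)
  expect_error(combine_views(list(J1, matrix(1, 3, 7)), list(y1, 1:3),
                             views = c(1, 2)), "inconsistent")
})

test_that("noiseless recovery: a single hot voxel is found by CW
           reconstruction", {
  # richer sampling (8 patterns, per-2x1 detector patches) so the consistent
  # noiseless system localizes sharply
  g <- small_greens(n_patterns = 8, group = c(1, 2))
  mask <- g$u0 > 0
  eta1 <- numeric(length(g$eta))
  hot <- which(g$eta > 0)[14] # a voxel inside the disc
  eta1[hot] <- 0.1
  em <- simulate_emission(eta1, 0.5, g$exc$fluence, g$gm,
                          g$sp$of_detector, 1)
  jcw <- build_jacobian(g$exc$fluence, g$gm, g$u0, g$sp$of_detector, 0.5, 1,
                        "cw", mask = mask)
  y <- cw_from_tpsf(em)[jcw$rows$measurement] / g$u0[jcw$rows$measurement]
  rec <- reconstruct_cw(jcw$J, y, iterations = 100)
  # consistent data: the reconstruction peaks on or next to the true voxel
  d <- dim(g$ph$labels)
  tidx <- tissue_indices(g$ph)
  pk <- arrayInd(tidx[which.max(rec$eta_hat)], d)
  tr <- arrayInd(tidx[hot], d)
  expect_lte(max(abs(pk - tr)), 1)
  # and the 50% isovolume centroid is within one voxel of the truth
  vol <- recon_to_volume(rec$eta_hat, g$ph)
  truth <- recon_to_volume(eta1, g$ph)
  cen <- centroid(isovolume_mask(vol), g$ph$voxel_mm)
  cen_true <- centroid(truth > 0, g$ph$voxel_mm)
  expect_lt(localization_error(cen, cen_true), g$ph$voxel_mm + 1e-9)
})

test_that("frame mapping: view-2 Green's functions reconstruct in the
           fixed spine frame", {
  # rotate the phantom, simulate in the laboratory frame, reorder rows by
  # the inverse rotation, reconstruct, compare against the view-1 truth
  ph <- small_phantom()
  detg <- small_detgrid()
  sp <- superpatch_layout(detg, 2, 3)
  spine_tidx <- tissue_indices(ph)
  eta_spine <- ph$eta[spine_tidx]
  ph2 <- apply_view(ph, view_transform(2))
  perm <- spinefmt:::.rot90_perm(dim(ph$labels), 1L)
  reidx <- match(perm[spine_tidx], tissue_indices(ph2))
  exc <- simulate_excitation(ph2, 3e4, 77, detectors = detg, n_patterns = 4,
                             pattern_width_mm = 6, nt = 96)
  gx <- lapply(exc$fluence, function(g) g[reidx, , drop = FALSE])
  gm <- lapply(seq_len(sp$n_patches), function(s)
    adjoint_emission_greens(ph2, sp$patches[[s]], 3e4,
                            derive_seed(77, 7L, s), nt = 96)[reidx, ,
                                                             drop = FALSE])
  u0 <- cw_from_tpsf(exc$tpsf)
  em <- simulate_emission(eta_spine, 0.5, gx, gm, sp$of_detector, 1)
  jcw <- build_jacobian(gx, gm, u0, sp$of_detector, 0.5, 1, "cw",
                        mask = u0 > 0)
  y <- cw_from_tpsf(em)[jcw$rows$measurement] / u0[jcw$rows$measurement]
  rec <- reconstruct_cw(jcw$J, y, iterations = 100)
  vol <- recon_to_volume(rec$eta_hat, ph)
  cen <- centroid(isovolume_mask(vol), ph$voxel_mm)
  # the reconstruction lands on the spine-frame inclusion
  expect_lt(localization_error(cen, inclusion_centroid(ph)),
            2 * ph$voxel_mm)
})
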