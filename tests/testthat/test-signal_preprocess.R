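# Volume censoring, DVARS, tissue masking, cleaning and band-pass.

test_that("a single FD exceedance removes the guard window around it", {
  fd <- rep(0, 10); fd[6] <- 0.9            # volume 6 (index 5 zero-based)
  mt <- motion_trace(fd, rep(0, 10))
  cen <- censor_volumes(mt)
  expect_equal(which(!cen$keep_mask), 5:8)  # previous + trigger + two next
  expect_equal(sum(cen$keep_mask), 6L)
  expect_equal(cen$retained_fraction, 0.6)
  expect_true(cen$include_subject)
})

test_that("guard windows clip at run boundaries and 50% retention is inclusive", {
  fd <- rep(0, 10); fd[10] <- 1
  dv <- rep(0, 10); dv[1] <- 5              # dvars can trigger volume 1
  mt <- structure(list(fd = fd, dvars = dv, n_volumes = 10L),
                  class = "motion_trace")
  cen <- censor_volumes(mt)
  expect_equal(sort(which(!cen$keep_mask)), c(1:3, 9:10))
  expect_equal(cen$retained_fraction, 0.5)
  expect_true(cen$include_subject)          # exactly 50% retained counts
  cen2 <- censor_volumes(mt, min_retained = 0.51)
  expect_false(cen2$include_subject)
})

test_that("scrubbing masks match the brute-force window-union oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(20:80, 1)
    mt <- random_motion_trace(n)
    cen <- censor_volumes(mt)
    expect_identical(cen$keep_mask, oracle_censor_mask(mt$fd, mt$dvars))
  }
})

test_that("censoring an already-censored trace changes nothing", {
  set.seed(7)
  for (rep in 1:20) {
    mt <- random_motion_trace(60, p_spike = 0.15)
    cen <- censor_volumes(mt)
    fd2 <- mt$fd[cen$keep_mask]; fd2[1] <- 0
    dv2 <- mt$dvars[cen$keep_mask]; dv2[1] <- 0
    cen2 <- censor_volumes(motion_trace(fd2, dv2))
    expect_true(all(cen2$keep_mask))
  }
})

test_that("motion trace constructor validates its invariants", {
  expect_error(motion_trace(numeric(), numeric()), "empty")
  expect_error(motion_trace(c(0, 1), c(0)), "same length")
  expect_error(motion_trace(c(0, -1), c(0, 1)), "non-negative")
  expect_error(motion_trace(c(0.2, 0.1), c(0, 1)), "first volume")
})

test_that("framewise displacement follows the Power formulation", {
  p <- matrix(0, 3, 6)
  p[2, ] <- c(0.1, -0.2, 0.05, 0.002, 0, -0.001)  # rotations in radians
  fd <- framewise_displacement(p)
  expect_equal(fd[1], 0)
  expect_equal(fd[2], 0.1 + 0.2 + 0.05 + 50 * (0.002 + 0.001))
  expect_equal(fd[3], fd[2])  # returning to zero moves by the same amount
})

test_that("DVARS matches hand computation and is scale invariant", {
  expect_equal(compute_dvars(matrix(5, 4, 6)), rep(0, 6))
  toy <- cbind(c(1, 2, 3, 4), c(2, 4, 1, 3))
  d <- c(1, 2, -2, -1)
  expect_equal(compute_dvars(toy), c(0, sd(d) / mean(toy) * 100))
  set.seed(1)
  vol <- array(abs(rnorm(4 * 4 * 2 * 8, 100, 10)), dim = c(4, 4, 2, 8))
  expect_equal(compute_dvars(vol), compute_dvars(vol * 10))
  mask <- array(runif(32) > 0.3, dim = c(4, 4, 2))
  expect_equal(compute_dvars(vol, mask), compute_dvars(vol * 10, mask))
  expect_error(compute_dvars(vol, array(FALSE, dim = c(4, 4, 2))), "mask")
  expect_error(compute_dvars(matrix(1, 4, 1)), "at least 2")
})

test_that("grey-matter masking keeps ties and never adds voxels", {
  p_gm <- c(0.6, 0.4, 0.3)
  p_wm <- c(0.3, 0.4, 0.5)
  p_csf <- c(0.1, 0.2, 0.2)
  labels <- c(10L, 20L, 30L)
  out <- mask_atlas_by_gm(labels, p_gm, p_wm, p_csf)
  expect_equal(out, c(10L, 20L, 0L))      # tie retained, strict < removed
  set.seed(3)
  for (rep in 1:20) {
    pg <- runif(50); pw <- runif(50); pc <- runif(50)
    mx <- pmax(pg, pw, pc)
    lab <- sample(0:90, 50, replace = TRUE)
    out <- mask_atlas_by_gm(lab, pg / mx, pw / mx, pc / mx)
    expect_true(all(out %in% c(0L, lab)))
    expect_true(all(out[out != 0] == lab[out != 0]))
  }
  expect_error(mask_atlas_by_gm(1:3, c(0.5, 0.5), c(0.1, 0.1), c(0.1, 0.1)),
               "identical shapes")
})

test_that("regional averaging means voxels by label and flags empty regions", {
  vox <- rbind(c(1, 2), c(3, 4), c(10, 20))
  lab <- c(1L, 1L, 2L)
  out <- regional_average(vox, lab)
  expect_equal(unname(out), rbind(c(2, 3), c(10, 20)))
  expect_warning(out2 <- regional_average(vox, lab, region_ids = c(1L, 5L)),
                 "zero retained voxels")
  expect_true(all(is.na(out2[2, ])))
})

test_that("nuisance regression residualizes and detrends jointly", {
  set.seed(11)
  x <- matrix(rnorm(5 * 50), 5, 50)
  run <- regional_run(x, tr = 1.6)
  # nuisance = the signal itself -> residual ~ 0
  self <- clean_regional_series(run, nuisance = t(x))
  expect_lt(max(abs(self$signals)), 1e-10)
  # a pure linear ramp is removed by the trend column
  ramp <- regional_run(matrix(rep(3 * (1:50) - 7, each = 4), 4, 50,
                              byrow = FALSE), tr = 1.6)
  expect_lt(max(abs(clean_regional_series(ramp)$signals)), 1e-10)
  # residuals orthogonal to the regressors (normal equations)
  nuis <- matrix(rnorm(50 * 3), 50, 3)
  res <- clean_regional_series(run, nuisance = nuis)
  expect_lt(max(abs(res$signals %*% cbind(1, 1:50, nuis))), 1e-8)
})

test_that("censored volumes are dropped before cleaning", {
  set.seed(12)
  x <- matrix(rnorm(3 * 40), 3, 40)
  keep <- rep(TRUE, 40); keep[10:15] <- FALSE
  run <- regional_run(x, tr = 1.6, keep_mask = keep)
  out <- clean_regional_series(run)
  expect_equal(ncol(out$signals), 34L)
  expect_true(all(out$keep_mask))
})

test_that("band-pass preserves the pass band and kills stop band and DC", {
  tr <- 1.6
  t <- (0:299) * tr
  inband <- regional_run(rbind(sin(2 * pi * 0.05 * t)), tr)
  out <- bandpass(inband)
  mid <- 60:240
  expect_lt(abs(sd(out$signals[1, mid]) / sd(inband$signals[1, mid]) - 1),
            0.05)
  stopband <- regional_run(rbind(sin(2 * pi * 0.2 * t)), tr)
  outs <- bandpass(stopband)
  expect_lt(sd(outs$signals[1, mid]) / sd(stopband$signals[1, mid]), 0.10)
  const <- regional_run(matrix(7, 2, 300), tr)
  expect_lt(max(abs(bandpass(const)$signals)), 1e-6)
  expect_error(bandpass(inband, low = 0), "band")
  expect_error(bandpass(inband, high = 0.4), "band")  # above Nyquist 0.3125
})

test_that("band-passing twice is close to band-passing once", {
  # exact on a mid-band tone, where the squared response is still ~ 1
  tr <- 1.6
  t <- (0:299) * tr
  tone <- regional_run(rbind(sin(2 * pi * 0.05 * t)), tr)
  once_t <- bandpass(tone)
  twice_t <- bandpass(once_t)
  mid <- 60:240
  expect_equal(sd(twice_t$signals[1, mid]), sd(once_t$signals[1, mid]),
               tolerance = 0.02)
  # broadband noise keeps some energy near the band edges, where the
  # re-applied order-4 roll-off shaves a little more: agreement is close
  # but not exact
  set.seed(5)
  run <- regional_run(matrix(rnorm(3 * 300), 3, 300), tr = 1.6)
  once <- bandpass(run)
  twice <- bandpass(once)
  for (i in 1:3)
    expect_gt(cor(once$signals[i, mid], twice$signals[i, mid]), 0.98)
})
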