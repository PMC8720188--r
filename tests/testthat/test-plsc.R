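# Dose-response PLSC: closed form, resampling inference, LOOCV.

test_that("the design standardizes both blocks across subjects", {
  set.seed(41)
  d <- build_design(matrix(rnorm(15 * 90), 15, 90), rnorm(15, 25, 9))
  expect_equal(dim(d$Xz), c(15L, 90L))
  expect_equal(dim(d$Yz), c(15L, 1L))
  expect_lt(max(abs(colMeans(d$Xz))), 1e-12)
  expect_lt(max(abs(apply(d$Xz, 2, sd) - 1)), 1e-12)
  expect_lt(abs(mean(d$Yz)), 1e-12)
  expect_equal(sd(d$Yz), 1)
  expect_error(build_design(matrix(rnorm(30), 6, 5), rep(25, 6)),
               "zero-variance outcome")
  X <- matrix(rnorm(30), 6, 5); X[, 3] <- 2
  expect_error(build_design(X, rnorm(6)), "region")
  expect_error(build_design(matrix(rnorm(8), 4, 2), rnorm(4)), "at least 5")
})

test_that("single-outcome saliences equal the normalized correlation vector", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(10:25, 1)
    p <- sample(5:40, 1)
    X <- matrix(rnorm(n * p), n, p)
    dose <- rnorm(n, 25, 9)
    f <- fit_plsc(build_design(X, dose))
    r <- vapply(seq_len(p), function(j) cor(dose, X[, j]), numeric(1))
    # with the outcome salience oriented positive, the brain saliences are
    # exactly the unit-normalized dose/region correlation vector
    v_oracle <- r / sqrt(sum(r^2))
    expect_equal(unname(f$V[, 1]), v_oracle, tolerance = 1e-10)
    expect_equal(unname(f$U[1, 1]), 1)
    expect_equal(f$S[1], sqrt(sum(r^2)), tolerance = 1e-10)
    # reconstruction R = U S V'
    expect_lt(max(abs(f$R - f$U %*% diag(f$S, nrow = length(f$S)) %*%
                        t(f$V))), 1e-10)
    expect_equal(sum(f$V[, 1]^2), 1, tolerance = 1e-12)
  }
})

test_that("duplicated imaging columns get equal saliences", {
  set.seed(43)
  X <- matrix(rnorm(12 * 6), 12, 6)
  X[, 4] <- X[, 2]
  f <- fit_plsc(build_design(X, rnorm(12)))
  expect_equal(unname(f$V[2, 1]), unname(f$V[4, 1]), tolerance = 1e-12)
})

test_that("salience concentrates on a region that carries the outcome", {
  set.seed(44)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10)
  dose <- X[, 6]
  f <- fit_plsc(build_design(X, dose))
  expect_equal(unname(which.max(abs(f$V[, 1]))), 6L)
  expect_gt(f$V[6, 1], 0.95)
})

test_that("latent scores are the projections of the standardized blocks", {
  set.seed(45)
  d <- build_design(matrix(rnorm(15 * 8), 15, 8), rnorm(15))
  f <- fit_plsc(d)
  expect_equal(f$Lx, d$Xz %*% f$V)
  expect_equal(f$Ly, d$Yz %*% f$U)
})

test_that("permutation test is deterministic under a seed and valid", {
  set.seed(46)
  sim <- simulate_plsc_design(15, 30, positive = 1:3, r = 0.9, seed = 5)
  f <- fit_plsc(build_design(sim$X, sim$dose))
  p1 <- permutation_test(f, 500, seed = 9)
  p2 <- permutation_test(f, 500, seed = 9)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_gt(p1$p_perm, 0)          # add-one smoothing keeps p positive
  expect_lt(p1$p_perm, 0.05)       # strong planted effect detected
  expect_length(p1$s_perm, 500)
  expect_warning(permutation_test(f, 50, seed = 1), "coarse")
})

test_that("vectorized single-outcome permutation equals the svd refit route", {
  set.seed(47)
  d <- build_design(matrix(rnorm(12 * 7), 12, 7), rnorm(12))
  f <- fit_plsc(d)
  set.seed(123)
  perms <- replicate(50, sample.int(d$n))
  s_oracle <- apply(perms, 2, function(ix)
    svd(crossprod(d$Yz[ix, , drop = FALSE], d$Xz) / (d$n - 1))$d[1])
  p <- permutation_test(f, 50, seed = 123) |> suppressWarnings()
  expect_equal(p$s_perm, s_oracle, tolerance = 1e-12)
})

test_that("bootstrap recovers planted salience signs and is seed-stable", {
  set.seed(48)
  sim <- simulate_plsc_design(15, 30, positive = 1:4, negative = 5:8,
                              r = 0.9, seed = 6)
  f <- fit_plsc(build_design(sim$X, sim$dose))
  b1 <- bootstrap_stability(f, 200, seed = 3)
  b2 <- bootstrap_stability(f, 200, seed = 3)
  expect_identical(b1$boot_p5, b2$boot_p5)
  expect_true(all(b1$robust_mask[1:4]))
  expect_true(all(b1$robust_mask[5:8]))
  expect_true(all(b1$boot_mean[1:4] > 0))
  expect_true(all(b1$boot_mean[5:8] < 0))
  # noise regions mostly not flagged
  expect_lt(mean(b1$robust_mask[9:30]), 0.25)
  # the ratio rule is available as an alternative
  br <- bootstrap_stability(f, 200, seed = 3, method = "ratio")
  expect_true(all(br$robust_mask[1:8]))
})

test_that("LOOCV scores track the full model when the relation is noiseless", {
  set.seed(49)
  z <- rnorm(15)
  a <- rnorm(10)
  X <- outer(z, a)                     # rank-1, deterministic dose relation
  f <- fit_plsc(build_design(X, z))
  cv <- loocv_scores(f)
  expect_gt(cv$r_lx, 0.99)
  expect_gt(cv$r_ly, 0.99)
  expect_equal(cv$n_excluded, 0L)
})

test_that("a global sign flip leaves LOOCV correlation magnitudes unchanged", {
  set.seed(50)
  sim <- simulate_plsc_design(15, 12, positive = 1:3, r = 0.8, seed = 8)
  f1 <- fit_plsc(build_design(sim$X, sim$dose))
  f2 <- fit_plsc(build_design(-sim$X, sim$dose))
  cv1 <- loocv_scores(f1)
  cv2 <- loocv_scores(f2)
  expect_equal(abs(cv1$r_lx), abs(cv2$r_lx), tolerance = 1e-10)
  expect_equal(abs(cv1$r_ly), abs(cv2$r_ly), tolerance = 1e-10)
})

test_that("cross-covariance scaling leaves saliences and p unchanged", {
  set.seed(51)
  d <- build_design(matrix(rnorm(15 * 8), 15, 8), rnorm(15))
  f <- fit_plsc(d)
  # same design with X scaled by a positive constant: standardization
  # absorbs it, so the fit is identical
  d2 <- build_design(d$X * 7.3, d$Y[, 1])
  f2 <- fit_plsc(d2)
  expect_equal(f$V, f2$V)
  expect_equal(f$S, f2$S)
  expect_identical(permutation_test(f, 200, seed = 2)$p_perm,
                   permutation_test(f2, 200, seed = 2)$p_perm)
})
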