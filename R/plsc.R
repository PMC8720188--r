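# Dose-response partial least squares correlation (PLSC): SVD of the
# outcome-by-imaging cross-covariance, with permutation significance,
# bootstrap salience stability, and leave-one-out score robustness.

standardize_columns <- function(m, what = "column") {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    nm <- colnames(m)
    lab <- if (is.null(nm)) bad else nm[bad]
    stop("zero-variance ", what, ": ", paste(lab, collapse = ", "))
  }
  list(z = sweep(sweep(m, 2L, mu), 2L, sdv, "/"), center = mu, scale = sdv)
}

#' Build a standardized PLSC design
#'
#' Pairs per-subject imaging variables (delta nodal strengths) with the
#' per-subject outcome (music-exposure dose). Both blocks are z-scored
#' across subjects; the standardization parameters are retained so
#' held-out subjects can be projected with the training normalization.
#'
#' @param deltas list of [delta_nodal_strength()] results, or a subjects x
#'   regions numeric matrix.
#' @param dose numeric outcome, one value per subject.
#' @return An object of class `plsc_design`: raw and standardized `X`
#'   (subjects x regions) and `Y` (subjects x 1), centers and scales.
#' @export
build_design <- function(deltas, dose) {
  X <- if (is.matrix(deltas)) deltas
       else do.call(rbind, lapply(deltas, function(d) {
         if (inherits(d, "nodal_delta")) d$delta_strength else as.numeric(d)
       }))
  n <- nrow(X)
  if (length(dose) != n) stop("one dose value per subject required")
  if (n < 5L) stop("need at least 5 subjects")
  if (is.null(colnames(X))) colnames(X) <- paste0("region_", seq_len(ncol(X)))
  sx <- standardize_columns(X, "imaging column (region)")
  sy <- standardize_columns(matrix(dose, ncol = 1,
                                   dimnames = list(NULL, "dose")), "outcome")
  structure(list(X = X, Y = matrix(dose, ncol = 1),
                 Xz = sx$z, Yz = sy$z,
                 x_center = sx$center, x_scale = sx$scale,
                 y_center = sy$center, y_scale = sy$scale,
                 n = n),
            class = "plsc_design")
}

#' Fit the PLSC model
#'
#' Computes the outcome-by-imaging cross-covariance `R = Y'X / (n - 1)` on
#' the standardized blocks and takes its SVD `R = U S V'`. With a single
#' outcome there is exactly one component: the brain saliences `V` are the
#' unit-normalized vector of dose/region correlations and `S` is that
#' vector's Euclidean norm. Latent scores are `Lx = X V`, `Ly = Y U`. The
#' sign is fixed by orienting the outcome salience positive, so a positive
#' brain salience means the region's delta strength rises with the dose.
#'
#' @param design a [build_design()] result.
#' @return An object of class `plsc_fit`: `R`, `U`, `S`, `V`, `Lx`, `Ly`,
#'   `design`.
#' @export
fit_plsc <- function(design) {
  stopifnot(inherits(design, "plsc_design"))
  fit <- plsc_core(design$Xz, design$Yz, design$n)
  structure(c(fit, list(design = design)), class = "plsc_fit")
}

plsc_core <- function(Xz, Yz, n) {
  R <- crossprod(Yz, Xz) / (n - 1)
  sv <- svd(R)
  U <- sv$u
  S <- sv$d
  V <- sv$v
  if (all(S == 0)) warning("degenerate design: cross-covariance is zero")
  # sign convention: with one outcome, orient the component so the outcome
  # salience is positive -- brain saliences then read as dose correlations
  # (positive salience = strength change rises with dose); with several
  # outcomes, make the largest-|salience| brain element positive
  if (ncol(U) == 1L && nrow(U) == 1L) {
    if (U[1L, 1L] < 0) {
      U[, 1L] <- -U[, 1L]
      V[, 1L] <- -V[, 1L]
    }
  } else {
    k <- which.max(abs(V[, 1L]))
    if (V[k, 1L] < 0) {
      V[, 1L] <- -V[, 1L]
      U[, 1L] <- -U[, 1L]
    }
  }
  rownames(V) <- colnames(Xz)
  list(R = R, U = U, S = S, V = V,
       Lx = Xz %*% V, Ly = Yz %*% U)
}

#' Permutation test of the PLSC component
#'
#' Refits after randomly permuting the outcome rows against the imaging
#' rows; the null statistic is the (first) singular value. The p-value uses
#' the add-one convention `p = (1 + #\{S_perm >= S_obs\}) / (1 + n_perm)`.
#'
#' @param fit a [fit_plsc()] result.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed for the permutation draws.
#' @return list with `p_perm`, `s_obs`, `s_perm` (null distribution).
#' @export
permutation_test <- function(fit, n_perm = 5000, seed = 1L) {
  stopifnot(inherits(fit, "plsc_fit"))
  if (n_perm < 100) warning("fewer than 100 permutations; p-value is coarse")
  d <- fit$design
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(d$n))
  if (ncol(d$Yz) == 1L) {
    # single outcome: S of each permuted fit is the norm of the permuted
    # cross-covariance row vector, so all permutations batch into one product
    Yperm <- matrix(d$Yz[perms], nrow = d$n)
    Rp <- crossprod(Yperm, d$Xz) / (d$n - 1)
    s_perm <- sqrt(rowSums(Rp^2))
  } else {
    s_perm <- apply(perms, 2L, function(ix) {
      svd(crossprod(d$Yz[ix, , drop = FALSE], d$Xz) / (d$n - 1))$d[1L]
    })
  }
  s_obs <- fit$S[1L]
  list(p_perm = (1 + sum(s_perm >= s_obs)) / (1 + n_perm),
       s_obs = s_obs, s_perm = s_perm)
}

#' Bootstrap stability of the brain saliences
#'
#' Resamples subjects with replacement, restandardizes and refits, aligns
#' each refit's sign to the reference fit, and summarizes every region's
#' salience by its bootstrap mean and 5th/95th percentiles. A salience is
#' *robust* when that interval excludes zero (`method = "percentile"`), or
#' when |bootstrap ratio| = |mean/SD| exceeds `ratio_threshold`
#' (`method = "ratio"`).
#'
#' @param fit a [fit_plsc()] result.
#' @param n_boot bootstrap samples (default 200).
#' @param seed RNG seed.
#' @param method robustness rule, `"percentile"` (default) or `"ratio"`.
#' @param ratio_threshold bootstrap-ratio cutoff (default 2.58) when
#'   `method = "ratio"`.
#' @return list with `boot_mean`, `boot_sd`, `boot_p5`, `boot_p95`,
#'   `robust_mask`, `n_redraws`, and the aligned `boot_V` draws.
#' @export
bootstrap_stability <- function(fit, n_boot = 200, seed = 1L,
                                method = c("percentile", "ratio"),
                                ratio_threshold = 2.58) {
  stopifnot(inherits(fit, "plsc_fit"))
  method <- match.arg(method)
  d <- fit$design
  v_ref <- fit$V[, 1L]
  set.seed(seed)
  boot_V <- matrix(NA_real_, n_boot, length(v_ref))
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      ix <- sample.int(d$n, replace = TRUE)
      ok <- all(apply(d$X[ix, , drop = FALSE], 2L, stats::sd) > 0) &&
        stats::sd(d$Y[ix, 1L]) > 0
      if (ok) break
      redraws <- redraws + 1L
    }
    sx <- standardize_columns(d$X[ix, , drop = FALSE])
    sy <- standardize_columns(d$Y[ix, , drop = FALSE])
    vb <- plsc_core(sx$z, sy$z, length(ix))$V[, 1L]
    if (sum(vb * v_ref) < 0) vb <- -vb
    boot_V[b, ] <- vb
  }
  if (redraws > 0.1 * n_boot)
    warning(redraws, " degenerate bootstrap samples redrawn (> 10%)")
  bm <- colMeans(boot_V)
  bs <- apply(boot_V, 2L, stats::sd)
  p5 <- apply(boot_V, 2L, stats::quantile, probs = 0.05, names = FALSE)
  p95 <- apply(boot_V, 2L, stats::quantile, probs = 0.95, names = FALSE)
  robust <- switch(method,
                   percentile = p5 > 0 | p95 < 0,
                   ratio = abs(bm / bs) >= ratio_threshold)
  names(robust) <- names(bm) <- names(bs) <- names(p5) <- names(p95) <-
    rownames(fit$V)
  list(boot_mean = bm, boot_sd = bs, boot_p5 = p5, boot_p95 = p95,
       robust_mask = robust, n_redraws = redraws, boot_V = boot_V,
       method = method)
}

#' Leave-one-out cross-validated latent scores
#'
#' For each fold, the model (including the column standardization) is
#' learnt on n - 1 subjects; the held-out subject is normalized with the
#' training parameters and projected on the training saliences to obtain
#' cross-validated `Lx`, `Ly`. Fold saliences are sign-aligned to the full
#' fit. The Pearson correlations between full-model and cross-validated
#' scores summarize robustness to left-out samples.
#'
#' @param fit a [fit_plsc()] result.
#' @return list with `scores` (data.frame: subject, lx_full, lx_cv,
#'   ly_full, ly_cv), `r_lx`, `r_ly`, and `n_excluded` folds.
#' @export
loocv_scores <- function(fit) {
  stopifnot(inherits(fit, "plsc_fit"))
  d <- fit$design
  if (d$n < 5L) stop("need at least 5 subjects for LOOCV")
  v_ref <- fit$V[, 1L]
  lx_cv <- ly_cv <- rep(NA_real_, d$n)
  excluded <- 0L
  for (i in seq_len(d$n)) {
    Xtr <- d$X[-i, , drop = FALSE]
    Ytr <- d$Y[-i, , drop = FALSE]
    if (any(apply(Xtr, 2L, stats::sd) == 0) || stats::sd(Ytr[, 1L]) == 0) {
      excluded <- excluded + 1L
      warning("fold ", i, " has a zero-variance column; excluded")
      next
    }
    sx <- standardize_columns(Xtr)
    sy <- standardize_columns(Ytr)
    f <- plsc_core(sx$z, sy$z, d$n - 1L)
    v <- f$V[, 1L]
    u <- f$U[, 1L]
    if (sum(v * v_ref) < 0) { v <- -v; u <- -u }
    x_te <- (d$X[i, ] - sx$center) / sx$scale
    y_te <- (d$Y[i, 1L] - sy$center) / sy$scale
    lx_cv[i] <- sum(x_te * v)
    ly_cv[i] <- sum(y_te * u)
  }
  ok <- !is.na(lx_cv)
  list(scores = data.frame(subject = seq_len(d$n),
                           lx_full = fit$Lx[, 1L], lx_cv = lx_cv,
                           ly_full = fit$Ly[, 1L], ly_cv = ly_cv),
       r_lx = stats::cor(fit$Lx[ok, 1L], lx_cv[ok]),
       r_ly = stats::cor(fit$Ly[ok, 1L], ly_cv[ok]),
       n_excluded = excluded)
}
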