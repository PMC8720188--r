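# Independent brute-force oracles used to pin the vectorized
# implementations, kept deliberately naive.

# scrubbing oracle: enumerate each trigger's guard window and union them
oracle_censor_mask <- function(fd, dvars, fd_thresh = 0.5, dvars_thresh = 3,
                               before = 1L, after = 2L) {
  n <- length(fd)
  removed <- integer()
  for (t in seq_len(n)) {
    if (fd[t] > fd_thresh || dvars[t] > dvars_thresh)
      removed <- union(removed, seq(max(1L, t - before), min(n, t + after)))
  }
  !(seq_len(n) %in% removed)
}

# naive double-loop accordance/discordance from the definition
oracle_accordance <- function(x, q_low = 0.158, q_high = 0.842) {
  nr <- nrow(x)
  U <- D <- matrix(0, nr, ncol(x))
  for (i in seq_len(nr)) {
    U[i, ] <- as.numeric(x[i, ] > quantile(x[i, ], q_high, names = FALSE))
    D[i, ] <- as.numeric(x[i, ] < quantile(x[i, ], q_low, names = FALSE))
  }
  acc <- dis <- matrix(0, nr, nr)
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      ni <- sqrt(sum(U[i, ]) + sum(D[i, ]))
      nj <- sqrt(sum(U[j, ]) + sum(D[j, ]))
      acc[i, j] <- (sum(U[i, ] * U[j, ]) + sum(D[i, ] * D[j, ])) / (ni * nj)
      dis[i, j] <- (sum(U[i, ] * D[j, ]) + sum(D[i, ] * U[j, ])) / (ni * nj)
    }
  }
  diag(acc) <- 1
  list(accordance = acc, discordance = dis)
}

random_motion_trace <- function(n, p_spike = 0.1) {
  fd <- c(0, abs(rnorm(n - 1, 0.2, 0.1)))
  dvars <- c(0, abs(rnorm(n - 1, 1.5, 0.6)))
  sp <- which(runif(n) < p_spike)
  sp <- sp[sp > 1]
  fd[sp] <- 0.5 + abs(rnorm(length(sp), 0.2, 0.1))
  sp2 <- which(runif(n) < p_spike)
  sp2 <- sp2[sp2 > 1]
  dvars[sp2] <- 3 + abs(rnorm(length(sp2), 0.5, 0.3))
  motion_trace(fd, dvars)
}

random_symmetric <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
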