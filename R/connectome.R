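# Accordance functional connectomes and weighted-graph nodal strength.

excursion_indicators <- function(x, q_low, q_high) {
  # per-region quantile thresholds on retained volumes only
  qh <- apply(x, 1L, stats::quantile, probs = q_high, names = FALSE)
  ql <- apply(x, 1L, stats::quantile, probs = q_low, names = FALSE)
  U <- x > qh
  D <- x < ql
  storage.mode(U) <- "double"
  storage.mode(D) <- "double"
  norms <- sqrt(rowSums(U) + rowSums(D))
  bad <- which(norms == 0)
  if (length(bad))
    stop("constant (no-excursion) regional series: region ",
         paste(bad, collapse = ", "))
  list(U = U, D = D, norms = norms)
}

run_matrix <- function(series) {
  if (inherits(series, "regional_run"))
    series$signals[, series$keep_mask, drop = FALSE]
  else as.matrix(series)
}

#' Accordance connectome
#'
#' Couples two regions by their simultaneous same-sign excursions: each
#' regional series is reduced to an upper-excursion indicator (signal above
#' its `q_high` within-region quantile) and a lower-excursion indicator
#' (below its `q_low` quantile), and
#' `accordance(i, j) = (u_i . u_j + d_i . d_j) / (||e_i|| ||e_j||)`
#' with `e_i` the concatenated indicator pair. Identical series score 1;
#' the default quantiles (0.158 / 0.842) mirror +/-1 SD tails of a normal.
#'
#' @param series a [regional_run()] (retained volumes are used) or a
#'   regions x volumes matrix.
#' @param q_low,q_high excursion quantiles in (0, 1), `q_low < q_high`.
#' @param run_id,subject_id optional identifiers carried on the result.
#' @return An object of class `connectome`: symmetric `weights` with unit
#'   diagonal and off-diagonal values in \[0, 1\], plus `region_ids`.
#' @export
accordance_matrix <- function(series, q_low = 0.158, q_high = 0.842,
                              run_id = NULL, subject_id = NULL) {
  x <- run_matrix(series)
  if (ncol(x) < 2L) stop("need at least 2 retained volumes")
  if (q_low <= 0 || q_high >= 1 || q_low >= q_high)
    stop("quantiles must satisfy 0 < q_low < q_high < 1")
  ind <- excursion_indicators(x, q_low, q_high)
  w <- (tcrossprod(ind$U) + tcrossprod(ind$D)) / tcrossprod(ind$norms)
  diag(w) <- 1
  ids <- if (inherits(series, "regional_run")) series$region_ids
         else seq_len(nrow(x))
  dimnames(w) <- list(ids, ids)
  structure(list(weights = w, region_ids = ids,
                 run_id = run_id, subject_id = subject_id),
            class = "connectome")
}

#' Discordance matrix
#'
#' Companion of [accordance_matrix()]: opposite-sign co-excursions,
#' `(u_i . d_j + d_i . u_j) / (||e_i|| ||e_j||)`. Sign-flipped zero-median
#' series score 1 with each other; identical series score 0. Diagnostic
#' output, not used by the downstream statistics.
#'
#' @inheritParams accordance_matrix
#' @return a `connectome`-shaped object (zero diagonal).
#' @export
discordance_matrix <- function(series, q_low = 0.158, q_high = 0.842,
                               run_id = NULL, subject_id = NULL) {
  x <- run_matrix(series)
  if (ncol(x) < 2L) stop("need at least 2 retained volumes")
  if (q_low <= 0 || q_high >= 1 || q_low >= q_high)
    stop("quantiles must satisfy 0 < q_low < q_high < 1")
  ind <- excursion_indicators(x, q_low, q_high)
  cross <- tcrossprod(ind$U, ind$D)
  w <- (cross + t(cross)) / tcrossprod(ind$norms)
  ids <- if (inherits(series, "regional_run")) series$region_ids
         else seq_len(nrow(x))
  dimnames(w) <- list(ids, ids)
  structure(list(weights = w, region_ids = ids,
                 run_id = run_id, subject_id = subject_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d regions%s%s\n", nrow(x$weights),
              if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id) else "",
              if (!is.null(x$run_id)) paste0(", ", x$run_id) else ""))
  invisible(x)
}

connectome_weights <- function(conn) {
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  if (nrow(w) != ncol(w) || !isTRUE(all.equal(w, t(w), tolerance = 1e-10)))
    stop("connectome weights must be a symmetric square matrix")
  w
}

#' Nodal strength of a weighted connectome
#'
#' Strength of region i is the sum of its edge weights to every other
#' region (the weighted degree); the diagonal is excluded.
#'
#' @param conn a `connectome` or symmetric square matrix.
#' @return named numeric vector, one strength per region.
#' @export
nodal_strength <- function(conn) {
  w <- connectome_weights(conn)
  s <- rowSums(w) - diag(w)
  names(s) <- rownames(w)
  s
}

#' Delta nodal strength between two runs
#'
#' Per-region change in nodal strength from the pre-stimulus to the
#' post-stimulus run (run 2 minus run 1); a positive value means the
#' region's total connectivity increased after the stimulus.
#'
#' @param run1,run2 `connectome`s of the same subject over the same
#'   region set.
#' @return An object of class `nodal_delta`: `delta_strength` (length
#'   n_regions) and `subject_id`.
#' @export
delta_nodal_strength <- function(run1, run2) {
  w1 <- connectome_weights(run1)
  w2 <- connectome_weights(run2)
  ids1 <- if (inherits(run1, "connectome")) run1$region_ids else rownames(w1)
  ids2 <- if (inherits(run2, "connectome")) run2$region_ids else rownames(w2)
  if (nrow(w1) != nrow(w2) || !identical(ids1, ids2))
    stop("the two runs cover different region sets")
  structure(list(delta_strength = nodal_strength(w2) - nodal_strength(w1),
                 region_ids = ids1,
                 subject_id = if (inherits(run1, "connectome"))
                   run1$subject_id else NULL),
            class = "nodal_delta")
}
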