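# Edge-wise pre/post inference per group and the between-group z-score
# fusion contrast.

#' Upper-triangle edge index table
#'
#' @param n_regions number of regions.
#' @return data.frame with columns `region_a`, `region_b` (`a < b`); for 90
#'   regions there are 4005 edges.
#' @export
edge_index <- function(n_regions) {
  idx <- which(upper.tri(diag(n_regions)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  data.frame(region_a = idx[ord, "row"], region_b = idx[ord, "col"])
}

#' Extract upper-triangle edge values across subjects
#'
#' @param conns list of `connectome`s (or symmetric matrices).
#' @return subjects x edges matrix, edges ordered as in [edge_index()].
#' @export
edge_values <- function(conns) {
  mats <- lapply(conns, connectome_weights)
  n <- nrow(mats[[1L]])
  sel <- which(upper.tri(diag(n)))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  out <- t(vapply(mats, function(m) m[sel][ord], numeric(length(sel))))
  out
}

#' Edge-wise one-sided paired t-tests between runs
#'
#' For every upper-triangle edge, a paired t-test of the post-stimulus
#' minus pre-stimulus connectivity differences across subjects, one-sided
#' for an *increase* in run 2 (p = P(T_{n-1} >= t)). Cohen's d for the
#' paired design is mean(diff) / sd(diff) with the unbiased (n - 1) sd.
#' Edges whose differences have zero variance are flagged degenerate and
#' carry `NA` statistics rather than an arbitrary p.
#'
#' @param conn_run1,conn_run2 lists of `connectome`s paired by subject
#'   (same order), n >= 3 subjects.
#' @return data.frame with columns `region_a`, `region_b`, `t`, `p`, `d`,
#'   `n`, `degenerate`.
#' @export
paired_edge_tests <- function(conn_run1, conn_run2) {
  if (length(conn_run1) != length(conn_run2))
    stop("runs must be paired by subject")
  n <- length(conn_run1)
  if (n < 3L) stop("need at least 3 subjects for a paired t-test")
  e1 <- edge_values(conn_run1)
  e2 <- edge_values(conn_run2)
  diffs <- e2 - e1
  m <- colMeans(diffs)
  s <- sqrt(colSums(sweep(diffs, 2L, m)^2) / (n - 1))
  degen <- s < .Machine$double.eps^0.5
  tval <- ifelse(degen, NA_real_, m / (s / sqrt(n)))
  pval <- stats::pt(tval, df = n - 1, lower.tail = FALSE)
  dval <- ifelse(degen, NA_real_, m / s)
  if (any(degen))
    warning(sum(degen), " degenerate (zero-variance) edge(s) excluded")
  nr <- nrow(connectome_weights(conn_run1[[1L]]))
  cbind(edge_index(nr),
        data.frame(t = tval, p = pval, d = dval, n = n, degenerate = degen))
}

#' Convert one-sided p-values to z-scores
#'
#' The standard-normal quantile of the upper-tail survival: `z = qnorm(1 -
#' p)`. Small p-values for an increase map to large positive z. Values of 0
#' or 1 are clamped to the nearest representable p with a warning.
#'
#' @param p one-sided p-values in (0, 1).
#' @return z-scores of the same length.
#' @export
p_to_z <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  eps <- .Machine$double.xmin
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    warning("p-values of 0 or 1 clamped to the nearest representable value")
    p <- pmin(pmax(p, eps), 1 - .Machine$double.eps / 2)
  }
  stats::qnorm(p, lower.tail = FALSE)
}

#' Fuse two groups' edge z-scores into a between-group contrast
#'
#' The difference of per-edge z-scores of the intervention and control
#' groups, rescaled to unit variance: `z_diff = (z_pm - z_pc) / sqrt(2)`.
#' Under the joint null with independent groups the raw difference has
#' variance 2 (variance sum law), so `z_diff` is standard normal and can be
#' thresholded directly (default 2.58, the upper 0.005 quantile).
#'
#' @param z_pm,z_pc per-edge z-scores, aligned edge order.
#' @param edges optional edge table as from [edge_index()].
#' @param threshold significance threshold in z units (default 2.58).
#' @return An object of class `z_contrast` with `z_pm`, `z_pc`, `z_diff`,
#'   `edges`, `threshold`.
#' @export
z_fusion <- function(z_pm, z_pc, edges = NULL, threshold = 2.58) {
  if (length(z_pm) != length(z_pc))
    stop("z-score vectors have different lengths")
  structure(list(z_pm = z_pm, z_pc = z_pc,
                 z_diff = (z_pm - z_pc) / sqrt(2),
                 edges = edges, threshold = threshold),
            class = "z_contrast")
}

#' Edges exceeding the fused z threshold
#'
#' @param zc a [z_fusion()] result.
#' @param threshold z threshold (default: the contrast's own).
#' @param region_names optional character vector mapping region index to
#'   label for readable output.
#' @return data.frame (`region_a`, `region_b`, `z_diff`) of edges with
#'   `z_diff >= threshold`, sorted by decreasing `z_diff`.
#' @export
significant_edges <- function(zc, threshold = NULL, region_names = NULL) {
  stopifnot(inherits(zc, "z_contrast"))
  if (is.null(threshold)) threshold <- zc$threshold
  edges <- zc$edges
  if (is.null(edges)) {
    # recover the region count from the edge count
    n <- (1 + sqrt(1 + 8 * length(zc$z_diff))) / 2
    edges <- edge_index(as.integer(round(n)))
  }
  keep <- which(!is.na(zc$z_diff) & zc$z_diff >= threshold)
  out <- data.frame(region_a = edges$region_a[keep],
                    region_b = edges$region_b[keep],
                    z_diff = zc$z_diff[keep])
  out <- out[order(-out$z_diff), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(region_names)) {
    out$region_a <- region_names[out$region_a]
    out$region_b <- region_names[out$region_b]
  }
  out
}
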