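# Synthetic three-group neonatal cohort generator: stationary Gaussian
# AR(1) regional BOLD with a run-2 covariance in which chosen edge
# couplings are increased, a music-exposure dose covariate driving planted
# nodal changes in the intervention group, and injected motion spikes.

#' Specify a synthetic cohort
#'
#' Defaults emulate a three-group neonatal music-intervention study: 16
#' full-term (FT), 15 preterm-control (PC) and 15 preterm-music (PM)
#' subjects, two 300-volume runs at TR 1.6 s over 90 atlas regions, and a
#' per-PM-subject exposure dose drawn from round(N(25, 8.92)) clamped to
#' \[7, 35\].
#'
#' @param n_per_group named counts for groups FT, PC, PM.
#' @param n_regions,n_volumes,tr dimensions of each run.
#' @param planted_edges named list (by group) of data.frames with columns
#'   `region_a`, `region_b`, `delta` giving run-2 coupling increments.
#' @param dose integer vector (length = PM group size) of prior exposure
#'   counts, or `NULL` to draw them.
#' @param dose_effect_nodes list with integer vectors `positive` and
#'   `negative`: regions whose planted run-2 increment magnitude scales
#'   with (positively) or against (negatively) the subject's dose.
#' @param dose_effect_r generating correlation between a dose-effect
#'   node's planted nodal delta and the dose (default 0.8).
#' @param dose_effect_delta baseline coupling increment per dose-effect
#'   edge (default 0.12).
#' @param dose_effect_partners how many partner regions each dose-effect
#'   node connects to (default 3).
#' @param dose_effect_scale relative modulation amplitude of the
#'   per-subject increment (default 0.5).
#' @param noise_sd overall signal scale.
#' @param spike_rate per-volume probability of a motion spike (default
#'   0.02, which with the 4-volume scrub window censors roughly a tenth of
#'   a 300-volume run).
#' @param ar_coef lag-1 autocorrelation of the regional signals.
#' @param block_size,block_cor baseline covariance structure: regions are
#'   correlated `block_cor` within consecutive blocks of `block_size`.
#' @param seed RNG seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(FT = 16L, PC = 15L, PM = 15L),
                        n_regions = 90L, n_volumes = 300L, tr = 1.6,
                        planted_edges = list(),
                        dose = NULL,
                        dose_effect_nodes = list(positive = integer(),
                                                 negative = integer()),
                        dose_effect_r = 0.8,
                        dose_effect_delta = 0.12,
                        dose_effect_partners = 3L,
                        dose_effect_scale = 0.5,
                        noise_sd = 1, spike_rate = 0.02,
                        ar_coef = 0.3, block_size = 10L, block_cor = 0.3,
                        seed = 1L) {
  groups <- c("FT", "PC", "PM")
  if (!all(groups %in% names(n_per_group)))
    stop("n_per_group must name counts for FT, PC and PM")
  for (g in names(planted_edges)) {
    pe <- planted_edges[[g]]
    if (!all(c("region_a", "region_b", "delta") %in% names(pe)))
      stop("planted_edges entries need columns region_a, region_b, delta")
    if (any(pe$region_a == pe$region_b))
      stop("planted edges must join two distinct regions")
    if (any(pe$region_a < 1 | pe$region_a > n_regions |
            pe$region_b < 1 | pe$region_b > n_regions))
      stop("planted edge region indices must lie in [1, n_regions]")
  }
  if (!is.null(dose)) {
    if (length(dose) != n_per_group[["PM"]])
      stop("dose must have one value per PM subject")
    if (any(dose < 7 | dose > 35))
      stop("dose values must lie in [7, 35]")
  }
  den <- unlist(dose_effect_nodes)
  if (length(den) && (any(den < 1 | den > n_regions)))
    stop("dose_effect_nodes indices must lie in [1, n_regions]")
  if (abs(dose_effect_r) > 1) stop("dose_effect_r must lie in [-1, 1]")
  structure(list(n_per_group = n_per_group[groups], n_regions = n_regions,
                 n_volumes = n_volumes, tr = tr,
                 planted_edges = planted_edges, dose = dose,
                 dose_effect_nodes = dose_effect_nodes,
                 dose_effect_r = dose_effect_r,
                 dose_effect_delta = dose_effect_delta,
                 dose_effect_partners = dose_effect_partners,
                 dose_effect_scale = dose_effect_scale,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 ar_coef = ar_coef, block_size = block_size,
                 block_cor = block_cor, seed = seed),
            class = "cohort_spec")
}

base_covariance <- function(n_regions, block_size, block_cor) {
  block <- (seq_len(n_regions) - 1L) %/% block_size
  sigma <- outer(block, block, function(a, b) ifelse(a == b, block_cor, 0))
  diag(sigma) <- 1
  sigma
}

# deterministic partner assignment for a dose-effect node: the next
# `k` regions (cyclically) that are not themselves effect nodes
dose_effect_partner_set <- function(node, k, n_regions, effect_nodes) {
  cand <- setdiff(((node + seq_len(n_regions) - 1L) %% n_regions) + 1L,
                  c(node, effect_nodes))
  cand[seq_len(min(k, length(cand)))]
}

# per-subject increment table for one run-2 covariance
subject_increments <- function(spec, group, u_subj) {
  inc <- spec$planted_edges[[group]]
  if (is.null(inc)) {
    inc <- data.frame(region_a = integer(), region_b = integer(),
                      delta = numeric())
  } else {
    inc <- inc[, c("region_a", "region_b", "delta")]
  }
  if (group == "PM" && !is.null(u_subj)) {
    eff <- spec$dose_effect_nodes
    all_nodes <- c(eff$positive, eff$negative)
    for (node in eff$positive) {
      partners <- dose_effect_partner_set(node, spec$dose_effect_partners,
                                          spec$n_regions, all_nodes)
      m <- spec$dose_effect_delta *
        max(0, 1 + spec$dose_effect_scale * u_subj)
      inc <- rbind(inc, data.frame(region_a = node, region_b = partners,
                                   delta = m))
    }
    for (node in eff$negative) {
      partners <- dose_effect_partner_set(node, spec$dose_effect_partners,
                                          spec$n_regions, all_nodes)
      m <- spec$dose_effect_delta *
        max(0, 1 - spec$dose_effect_scale * u_subj)
      inc <- rbind(inc, data.frame(region_a = node, region_b = partners,
                                   delta = m))
    }
  }
  inc
}

apply_increments <- function(sigma, inc) {
  for (k in seq_len(nrow(inc))) {
    i <- inc$region_a[k]; j <- inc$region_b[k]
    sigma[i, j] <- sigma[i, j] + inc$delta[k]
    sigma[j, i] <- sigma[i, j]
  }
  sigma
}

chol_or_fail <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("run-2 covariance is not positive definite after planting the ",
         "requested coupling increments; lower delta_coupling or reduce ",
         "the number of planted edges per region")
  ch
}

# stationary Gaussian AR(1) with cross-sectional covariance chol factor `ch`
sample_ar1 <- function(ch, n_volumes, phi, scale) {
  p <- ncol(ch)
  innov <- crossprod(ch, matrix(stats::rnorm(p * n_volumes), p))
  x <- matrix(0, p, n_volumes)
  x[, 1L] <- innov[, 1L]
  a <- sqrt(1 - phi^2)
  for (t in 2:n_volumes) x[, t] <- phi * x[, t - 1L] + a * innov[, t]
  x * scale
}

sample_motion <- function(n_volumes, spike_rate, fd_thresh = 0.5,
                          dvars_thresh = 3) {
  fd <- c(0, abs(stats::rnorm(n_volumes - 1L, 0.15, 0.06)))
  dvars <- c(0, abs(stats::rnorm(n_volumes - 1L, 1.2, 0.35)))
  spikes <- which(stats::runif(n_volumes) < spike_rate)
  spikes <- spikes[spikes > 1L]
  if (length(spikes)) {
    fd[spikes] <- fd_thresh + abs(stats::rnorm(length(spikes), 0.3, 0.1))
    dvars[spikes] <- dvars_thresh + abs(stats::rnorm(length(spikes), 1, 0.4))
  }
  list(trace = motion_trace(fd, dvars), spikes = spikes)
}

#' Generate a synthetic cohort
#'
#' Run-1 signals are drawn from a stationary zero-mean Gaussian AR(1)
#' process with a block-structured baseline covariance; run-2 signals come
#' from the same process with each planted edge's coupling increased. For
#' PM subjects the planted increments on the dose-effect nodes are
#' modulated per subject so that the generating correlation between the
#' planted nodal delta and the dose equals `dose_effect_r`. Motion spikes
#' add a global intensity jump and an FD/DVARS exceedance at the same
#' volume.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list of subjects, each
#'   with `group`, `run1`, `run2` ([regional_run()]), `motion1`, `motion2`
#'   ([motion_trace()]), `dose` (PM only) and `ground_truth` (the planted
#'   increments and implied nodal deltas).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sigma1 <- base_covariance(spec$n_regions, spec$block_size, spec$block_cor)
  ch1 <- chol(sigma1)

  n_pm <- spec$n_per_group[["PM"]]
  dose <- spec$dose
  if (is.null(dose))
    dose <- pmin(35, pmax(7, round(stats::rnorm(n_pm, 25, 8.92))))
  has_effect <- length(unlist(spec$dose_effect_nodes)) > 0
  u <- rep(NA_real_, n_pm)
  if (has_effect) {
    z <- as.numeric(scale(dose))
    eta <- stats::rnorm(n_pm)
    u <- spec$dose_effect_r * z +
      sqrt(1 - spec$dose_effect_r^2) * eta
  }

  subjects <- list()
  sid <- 0L
  for (g in names(spec$n_per_group)) {
    for (k in seq_len(spec$n_per_group[[g]])) {
      sid <- sid + 1L
      u_subj <- if (g == "PM" && has_effect) u[k] else NULL
      inc <- subject_increments(spec, g, u_subj)
      ch2 <- if (nrow(inc)) chol_or_fail(apply_increments(sigma1, inc))
             else ch1
      sig1 <- sample_ar1(ch1, spec$n_volumes, spec$ar_coef, spec$noise_sd)
      sig2 <- sample_ar1(ch2, spec$n_volumes, spec$ar_coef, spec$noise_sd)
      mo1 <- sample_motion(spec$n_volumes, spec$spike_rate)
      mo2 <- sample_motion(spec$n_volumes, spec$spike_rate)
      jump <- 3 * spec$noise_sd
      if (length(mo1$spikes)) sig1[, mo1$spikes] <- sig1[, mo1$spikes] + jump
      if (length(mo2$spikes)) sig2[, mo2$spikes] <- sig2[, mo2$spikes] + jump
      nodal <- numeric(spec$n_regions)
      if (nrow(inc)) {
        for (r in seq_len(nrow(inc))) {
          nodal[inc$region_a[r]] <- nodal[inc$region_a[r]] + inc$delta[r]
          nodal[inc$region_b[r]] <- nodal[inc$region_b[r]] + inc$delta[r]
        }
      }
      subjects[[sid]] <- structure(
        list(id = sprintf("%s_%02d", g, k), group = g,
             run1 = regional_run(sig1, spec$tr),
             run2 = regional_run(sig2, spec$tr),
             motion1 = mo1$trace, motion2 = mo2$trace,
             spikes1 = mo1$spikes, spikes2 = mo2$spikes,
             dose = if (g == "PM") dose[k] else NA_integer_,
             ground_truth = list(edges = inc, nodal_delta = nodal)),
        class = "synthetic_subject")
    }
  }
  structure(list(subjects = subjects, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("<synthetic_cohort>",
      paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
      sprintf("| %d regions x %d volumes, TR %g s\n",
              x$spec$n_regions, x$spec$n_volumes, x$spec$tr))
  invisible(x)
}

#' Report the planted (ground-truth) effects of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return list of two data.frames: `edges` (subject, group, region_a,
#'   region_b, delta — one row per planted edge per subject) and `dose`
#'   (PM subjects: subject, dose, node, sign, true_nodal_delta,
#'   generating_r).
#' @export
ground_truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  spec <- cohort$spec
  edges <- do.call(rbind, lapply(cohort$subjects, function(s) {
    e <- s$ground_truth$edges
    if (nrow(e) == 0L) return(NULL)
    cbind(data.frame(subject = s$id, group = s$group), e)
  }))
  if (is.null(edges))
    edges <- data.frame(subject = character(), group = character(),
                        region_a = integer(), region_b = integer(),
                        delta = numeric())
  eff <- spec$dose_effect_nodes
  dose_rows <- list()
  for (s in cohort$subjects) {
    if (s$group != "PM") next
    for (node in eff$positive)
      dose_rows[[length(dose_rows) + 1L]] <- data.frame(
        subject = s$id, dose = s$dose, node = node, sign = 1L,
        true_nodal_delta = s$ground_truth$nodal_delta[node],
        generating_r = spec$dose_effect_r)
    for (node in eff$negative)
      dose_rows[[length(dose_rows) + 1L]] <- data.frame(
        subject = s$id, dose = s$dose, node = node, sign = -1L,
        true_nodal_delta = s$ground_truth$nodal_delta[node],
        generating_r = spec$dose_effect_r)
  }
  dose_tab <- if (length(dose_rows)) do.call(rbind, dose_rows)
              else data.frame(subject = character(), dose = integer(),
                              node = integer(), sign = integer(),
                              true_nodal_delta = numeric(),
                              generating_r = numeric())
  list(edges = edges, dose = dose_tab)
}

#' Simulate a PLSC design with planted dose-correlated regions
#'
#' Direct design-level generator for calibration and recovery studies of
#' the PLSC stage: planted columns are `sign * (r * z_dose +
#' sqrt(1 - r^2) * noise)` so their generating correlation with the dose
#' is exactly `r` in law; remaining columns are independent noise.
#'
#' @param n subjects (default 15).
#' @param n_regions imaging columns (default 90).
#' @param positive,negative integer vectors of planted column indices.
#' @param r generating dose correlation of the planted columns.
#' @param seed RNG seed.
#' @return list with `X` (n x n_regions), `dose`, `positive`, `negative`.
#' @export
simulate_plsc_design <- function(n = 15L, n_regions = 90L,
                                 positive = integer(), negative = integer(),
                                 r = 0.9, seed = 1L) {
  set.seed(seed)
  repeat {
    dose <- pmin(35, pmax(7, round(stats::rnorm(n, 25, 8.92))))
    if (stats::sd(dose) > 0) break
  }
  z <- as.numeric(scale(dose))
  X <- matrix(stats::rnorm(n * n_regions), n, n_regions)
  for (j in positive) X[, j] <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
  for (j in negative) X[, j] <- -(r * z + sqrt(1 - r^2) * stats::rnorm(n))
  colnames(X) <- paste0("region_", seq_len(n_regions))
  list(X = X, dose = dose, positive = positive, negative = negative, r = r)
}

#' Write a cohort to per-subject TSV signal matrices plus a manifest
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame (subject, group, dose,
#'   run1_file, run2_file, motion1_file, motion2_file).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    files <- c(run1 = paste0(s$id, "_run1.tsv"),
               run2 = paste0(s$id, "_run2.tsv"),
               motion1 = paste0(s$id, "_motion1.tsv"),
               motion2 = paste0(s$id, "_motion2.tsv"))
    for (r in c("run1", "run2"))
      utils::write.table(format(s[[r]]$signals, digits = 8, trim = TRUE),
                         file.path(dir, files[[r]]), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    for (m in c("motion1", "motion2")) {
      tr <- s[[m]]
      utils::write.table(
        data.frame(volume = seq_len(tr$n_volumes),
                   fd_mm = format(tr$fd, digits = 8, trim = TRUE),
                   dvars_pct = format(tr$dvars, digits = 8, trim = TRUE)),
        file.path(dir, files[[m]]), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    data.frame(subject = s$id, group = s$group, dose = s$dose,
               run1_file = files[["run1"]], run2_file = files[["run2"]],
               motion1_file = files[["motion1"]],
               motion2_file = files[["motion2"]])
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "cohort_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
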