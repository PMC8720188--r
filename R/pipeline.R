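# Orchestration: synthetic cohort (or file ingest) -> censoring ->
# cleaning -> connectomes -> group contrast -> PLSC, with deterministic
# TSV outputs and a run manifest.

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort (or the
#'   cohort structure expected from files).
#' @param fd_thresh,dvars_thresh censoring thresholds (mm, percent).
#' @param scrub_before,scrub_after guard-window extent around a trigger.
#' @param min_retained minimum retained fraction for subject inclusion.
#' @param band band-pass edges in Hz.
#' @param q_low,q_high accordance excursion quantiles.
#' @param p_report per-group reporting threshold on the one-sided p.
#' @param z_threshold fused-contrast threshold in z units.
#' @param n_perm,n_boot PLSC resampling sizes.
#' @param run_plsc run the dose-response PLSC stage (needs PM doses).
#' @param out_dir output directory, or `NULL` for no file output.
#' @param seed seed for the resampling stages (the cohort uses its own).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            fd_thresh = 0.5, dvars_thresh = 3,
                            scrub_before = 1L, scrub_after = 2L,
                            min_retained = 0.5,
                            band = c(0.01, 0.1),
                            q_low = 0.158, q_high = 0.842,
                            p_report = 0.001, z_threshold = 2.58,
                            n_perm = 5000L, n_boot = 200L,
                            run_plsc = TRUE, out_dir = NULL, seed = 1L) {
  structure(list(cohort = cohort, fd_thresh = fd_thresh,
                 dvars_thresh = dvars_thresh, scrub_before = scrub_before,
                 scrub_after = scrub_after, min_retained = min_retained,
                 band = band, q_low = q_low, q_high = q_high,
                 p_report = p_report, z_threshold = z_threshold,
                 n_perm = n_perm, n_boot = n_boot, run_plsc = run_plsc,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  plain <- config
  plain$out_dir <- NULL
  js <- jsonlite::toJSON(unclass(plain), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

# censor + clean + band-pass + accordance for one run of one subject
process_run <- function(signals, tr, motion, config) {
  cen <- censor_volumes(motion, config$fd_thresh, config$dvars_thresh,
                        config$scrub_before, config$scrub_after,
                        config$min_retained)
  if (!cen$include_subject)
    return(list(censor = cen, connectome = NULL))
  run <- regional_run(signals, tr, keep_mask = cen$keep_mask)
  run <- clean_regional_series(run)
  run <- bandpass(run, config$band[1L], config$band[2L])
  list(censor = cen,
       connectome = accordance_matrix(run, config$q_low, config$q_high))
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, censors and cleans every run, builds
#' accordance connectomes, performs the per-group paired edge tests, fuses
#' the PM and PC z-scores into the between-group contrast, and runs the
#' dose-response PLSC on the PM group. All stage outputs are returned and,
#' when `out_dir` is set, written as TSV/JSON with a run manifest.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-generated [generate_cohort()] result
#'   (defaults to generating one from `config$cohort`).
#' @return invisibly, a list with `connectomes`, `group_tests`, `fusion`,
#'   `plsc`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)

  conns <- list()
  excluded <- character()
  censored_volumes <- 0L
  for (s in cohort$subjects) {
    p1 <- process_run(s$run1$signals, s$run1$tr, s$motion1, config)
    p2 <- process_run(s$run2$signals, s$run2$tr, s$motion2, config)
    censored_volumes <- censored_volumes + p1$censor$n_censored +
      p2$censor$n_censored
    if (is.null(p1$connectome) || is.null(p2$connectome)) {
      excluded <- c(excluded, s$id)
      message("pipeline: subject ", s$id,
              " excluded (less than 50% of volumes retained)")
      next
    }
    conns[[s$id]] <- list(group = s$group, dose = s$dose,
                          run1 = p1$connectome, run2 = p2$connectome)
  }

  groups <- vapply(conns, `[[`, "", "group")
  group_tests <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3L) {
      message("pipeline: group ", g, " has fewer than 3 usable subjects; ",
              "edge tests skipped")
      next
    }
    group_tests[[g]] <- paired_edge_tests(
      lapply(conns[idx], `[[`, "run1"),
      lapply(conns[idx], `[[`, "run2"))
  }

  fusion <- NULL
  if (all(c("PM", "PC") %in% names(group_tests))) {
    tpm <- group_tests$PM
    tpc <- group_tests$PC
    ok <- !tpm$degenerate & !tpc$degenerate
    z_pm <- ifelse(ok, p_to_z(pmin(pmax(tpm$p, .Machine$double.xmin),
                                   1 - 1e-16)), NA_real_)
    z_pc <- ifelse(ok, p_to_z(pmin(pmax(tpc$p, .Machine$double.xmin),
                                   1 - 1e-16)), NA_real_)
    fusion <- z_fusion(z_pm, z_pc, edges = tpm[, c("region_a", "region_b")],
                       threshold = config$z_threshold)
  }

  plsc <- NULL
  pm_idx <- which(groups == "PM")
  doses <- vapply(conns[pm_idx], `[[`, numeric(1), "dose")
  if (config$run_plsc && length(pm_idx) >= 5L && !anyNA(doses) &&
      stats::sd(doses) > 0) {
    deltas <- lapply(conns[pm_idx], function(cc)
      delta_nodal_strength(cc$run1, cc$run2))
    design <- build_design(deltas, doses)
    fit <- fit_plsc(design)
    perm <- permutation_test(fit, config$n_perm, seed = config$seed + 1L)
    boot <- bootstrap_stability(fit, config$n_boot, seed = config$seed + 2L)
    cv <- loocv_scores(fit)
    plsc <- list(fit = fit, perm = perm, boot = boot, cv = cv)
  } else if (config$run_plsc) {
    message("pipeline: PLSC stage skipped (needs >= 5 PM subjects with ",
            "a varying dose)")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("neofc")),
    seed = config$seed, cohort_seed = config$cohort$seed,
    config_hash = config_hash(config),
    n_subjects = length(cohort$subjects),
    n_retained = length(conns), excluded = excluded,
    volumes_censored = censored_volumes,
    edges_tested = if (length(group_tests))
      nrow(group_tests[[1L]]) else 0L,
    groups = as.list(table(groups)))

  result <- structure(list(connectomes = conns, group_tests = group_tests,
                           fusion = fusion, plsc = plsc, manifest = manifest,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- render_tables(result)
  for (nm in names(tabs$group_tables))
    write_tsv(tabs$group_tables[[nm]],
              file.path(out_dir, paste0("edges_", nm, ".tsv")))
  if (!is.null(tabs$fused_table))
    write_tsv(tabs$fused_table, file.path(out_dir, "edges_fused_PMvsPC.tsv"))
  if (!is.null(tabs$salience_table))
    write_tsv(tabs$salience_table, file.path(out_dir, "plsc_saliences.tsv"))
  if (!is.null(result$plsc)) {
    sc <- result$plsc$cv$scores
    sc[-1L] <- lapply(sc[-1L], fmt_num)
    write_tsv(sc, file.path(out_dir, "plsc_scores.tsv"))
    summary <- list(singular_value = result$plsc$fit$S[1L],
                    p_perm = result$plsc$perm$p_perm,
                    r_lx_cv = result$plsc$cv$r_lx,
                    r_ly_cv = result$plsc$cv$r_ly)
    jsonlite::write_json(summary, file.path(out_dir, "plsc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Region labels of the 90-region neonatal atlas parcellation
#'
#' @return data.frame with columns `index`, `label`, `name` following the
#'   90-region automated-anatomical-labelling scheme used for neonatal
#'   atlases; users may substitute their own lookup of the same shape.
#' @export
region_labels <- function() {
  utils::read.delim(system.file("extdata", "aal90_regions.tsv",
                                package = "neofc"),
                    stringsAsFactors = FALSE)
}

#' Publication-style tables from a pipeline run
#'
#' Per-group tables list the edges whose one-sided p falls below the
#' reporting threshold (Region | Region | p value | Cohen's d, ascending
#' p); the fused table lists edges at or above the z threshold (Region |
#' Region | z-score difference, descending); the salience table reports
#' per-region PLSC saliences with bootstrap summaries.
#'
#' @param result a [run_pipeline()] result.
#' @param region_names optional region-name lookup (default: the packaged
#'   90-region table when it matches the region count, else indices).
#' @return list with `group_tables`, `fused_table`, `salience_table`.
#' @export
render_tables <- function(result, region_names = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  config <- result$config
  n_regions <- config$cohort$n_regions
  if (is.null(region_names)) {
    region_names <- if (n_regions == 90L) region_labels()$name
                    else as.character(seq_len(n_regions))
  }
  group_tables <- lapply(result$group_tests, function(tt) {
    keep <- which(!tt$degenerate & tt$p < config$p_report)
    out <- tt[keep, , drop = FALSE]
    out <- out[order(out$p), , drop = FALSE]
    data.frame(region_1 = region_names[out$region_a],
               region_2 = region_names[out$region_b],
               p_value = fmt_num(out$p),
               cohens_d = fmt_num(out$d))
  })
  fused_table <- NULL
  if (!is.null(result$fusion)) {
    se <- significant_edges(result$fusion, region_names = region_names)
    fused_table <- data.frame(region_1 = se$region_a, region_2 = se$region_b,
                              z_score_difference = fmt_num(se$z_diff))
  }
  salience_table <- NULL
  if (!is.null(result$plsc)) {
    b <- result$plsc$boot
    salience_table <- data.frame(
      region = region_names[seq_along(b$boot_mean)],
      salience = fmt_num(result$plsc$fit$V[, 1L]),
      boot_mean = fmt_num(b$boot_mean),
      boot_p5 = fmt_num(b$boot_p5),
      boot_p95 = fmt_num(b$boot_p95),
      robust = b$robust_mask)
  }
  list(group_tables = group_tables, fused_table = fused_table,
       salience_table = salience_table)
}
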