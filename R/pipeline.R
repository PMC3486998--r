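#' Five-number summary for report rows
#'
#' Median, quartiles (linear interpolation between order statistics, the
#' convention used pipeline-wide) and range.
#'
#' @param values numeric vector, length `>= 1`.
#' @return Named numeric: `median`, `q25`, `q75`, `min`, `max`.
#' @export
#' @examples
#' summarize_table(c(1, 2, 3, 4)) # median 2.5, q25 1.75, q75 3.25
summarize_table <- function(values) {
  if (length(values) < 1) stop("empty input")
  if (anyNA(values)) stop("missing values are not allowed")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3],
    min = min(values), max = max(values))
}

# Summary block for one measure x condition cell of the report.
condition_block <- function(ct1, ct2) {
  d <- paired_differences(ct1, ct2)
  ba <- bland_altman(d, pair_means = (ct1 + ct2) / 2)
  list(n = length(d),
       baseline = as.list(summarize_table(ct1)),
       repeat_ct = as.list(summarize_table(ct2)),
       mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
       loa_low = ba$loa_low, loa_high = ba$loa_high,
       ccc = if (stats::var(ct1) > 0 && stats::var(ct2) > 0)
         concordance_correlation(ct1, ct2) else NA_real_,
       points = ba$points)
}

# Repeat-examination agreement analysis of a (corrected) measures table.
agreement_report <- function(measures, alpha = 0.05) {
  m1 <- measures[measures$visit == 1, ]
  m2 <- measures[measures$visit == 2, ]
  m2 <- m2[match(m1$subject_id, m2$subject_id), ]
  specs <- list(
    exp856 = list(col = "exp856_pct", corr = "exp856_volcorr_pct",
                  dv = m1$v_exp_L - m2$v_exp_L),
    ei_ratio = list(col = "ei_ratio_pct", corr = "ei_ratio_volcorr_pct",
                    dv = m1$v_exhaled_L - m2$v_exhaled_L))
  out <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    ct1 <- m1[[sp$col]]; ct2 <- m2[[sp$col]]
    labels <- breath_hold_subgroups(sp$dv)
    inf <- labels == "inferior"
    res <- list(
      uncorrected = condition_block(ct1, ct2),
      volume_corrected = condition_block(m1[[sp$corr]], m2[[sp$corr]]),
      inferior = condition_block(ct1[inf], ct2[inf]),
      superior = condition_block(ct1[!inf], ct2[!inf]))
    d_unc <- paired_differences(ct1, ct2)
    d_cor <- paired_differences(m1[[sp$corr]], m2[[sp$corr]])
    so <- sandvik_olsson(d_unc, d_cor)
    # zero-variation verification runs have no dispersion to compare
    lv <- tryCatch(levene_test(d_unc[inf], d_unc[!inf]),
                   error = function(e) list(statistic = NA_real_,
                                            p = NA_real_, degenerate = TRUE))
    res$tests <- list(
      volume_correction = list(test = "Sandvik-Olsson", rho = so$rho,
                               p = so$p, method = so$method,
                               significant = so$p < alpha),
      subgroup = list(test = "Levene", statistic = lv$statistic, p = lv$p,
                      degenerate = isTRUE(lv$degenerate),
                      significant = !is.na(lv$p) && lv$p < alpha))
    res$subgroup_n <- list(inferior = sum(inf), superior = sum(!inf))
    res
  })
  names(out) <- names(specs)
  out
}

report_points_table <- function(report) {
  rows <- list()
  for (meas in names(report)) {
    for (cond in c("uncorrected", "volume_corrected", "inferior", "superior")) {
      p <- report[[meas]][[cond]]$points
      if (!is.null(p))
        rows[[length(rows) + 1L]] <- data.frame(
          measure = meas, condition = cond, mean = p$mean, diff = p$diff)
    }
  }
  do.call(rbind, rows)
}

report_summary_table <- function(report) {
  rows <- list()
  for (meas in names(report)) {
    for (cond in c("uncorrected", "volume_corrected", "inferior", "superior")) {
      b <- report[[meas]][[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = meas, condition = cond, n = b$n,
        baseline_median = b$baseline$median, baseline_q25 = b$baseline$q25,
        baseline_q75 = b$baseline$q75, baseline_min = b$baseline$min,
        baseline_max = b$baseline$max,
        repeat_median = b$repeat_ct$median, repeat_q25 = b$repeat_ct$q25,
        repeat_q75 = b$repeat_ct$q75, repeat_min = b$repeat_ct$min,
        repeat_max = b$repeat_ct$max,
        mean_diff = b$mean_diff, loa_low = b$loa_low, loa_high = b$loa_high,
        ccc = b$ccc)
    }
  }
  do.call(rbind, rows)
}

strip_points <- function(report) {
  for (meas in names(report))
    for (cond in c("uncorrected", "volume_corrected", "inferior", "superior"))
      report[[meas]][[cond]]$points <- NULL
  report
}

#' Phantom quality-control run
#'
#' Simulates repeated phantom acquisitions, measures the foam ROI in each
#' session and compares per-session deviations from the nominal foam value
#' against an acceptance band.
#'
#' @param spec a [phantom_spec()].
#' @param n_sessions number of sessions.
#' @param band acceptance band in HU (default 4, a typical vendor stability
#'   range); a session whose foam ROI mean deviates from the nominal value by
#'   more than this is flagged.
#' @param roi_center,roi_diameter ROI placement (mm); the default sits in the
#'   foam between the two cylinders.
#' @param seed optional RNG seed.
#' @return Data frame with one row per session (`session`, `foam_mean_hu`,
#'   `deviation_hu`, `flagged`); attributes `overall_mean`, `overall_sd` and
#'   `pass` (no session flagged).
#' @export
phantom_qc <- function(spec, n_sessions = 20L, band = 4,
                       roi_center = c(0, 0, 0), roi_diameter = 20,
                       seed = NULL) {
  sessions <- generate_phantom(spec, n_sessions, seed = seed)
  means <- vapply(sessions, phantom_roi_mean, numeric(1),
                  center = roi_center, diameter = roi_diameter)
  dev <- means - spec$foam_mean
  out <- data.frame(session = seq_len(n_sessions), foam_mean_hu = means,
                    deviation_hu = dev, flagged = abs(dev) > band)
  attr(out, "overall_mean") <- mean(means)
  attr(out, "overall_sd") <- if (n_sessions > 1) stats::sd(means) else 0
  attr(out, "pass") <- !any(out$flagged)
  out
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full repeatability pipeline
#'
#' Orchestrates generate, quantify, volume-correct, analyse and report. In
#' `"full"` mode the synthetic cohort is generated in memory; `"generate"`
#' writes a cohort to disk and stops; `"analyse"` reads a previously written
#' cohort directory; `"phantom-qc"` runs the phantom monitor only. Identical
#' configuration and seed yield an identical report.
#'
#' @param config a [cohort_config()]; its `seed` drives all randomness.
#' @param mode one of `"full"`, `"generate"`, `"analyse"`, `"phantom-qc"`.
#' @param outdir optional output directory; when given, the report JSON, the
#'   summary table CSV, the Bland-Altman points CSV and the measures CSV are
#'   written there (atomically for the JSON).
#' @param cohort_dir cohort directory for `"generate"` (destination) and
#'   `"analyse"` (source).
#' @param smooth_sd_mm noise-filter kernel sd in mm.
#' @param segmentation `"mask"` (generator ground truth; default) or
#'   `"threshold"`.
#' @param phantom a [phantom_spec()] for `"phantom-qc"` mode.
#' @param n_sessions sessions for `"phantom-qc"` mode.
#' @param verbose log per-stage progress and timing via `message()`.
#' @return For analysis modes, an object of class `agreement_report`: a list
#'   with `provenance`, `exclusions`, per-measure condition blocks and test
#'   results, plus the `measures` table and `summary` table as attributes.
#'   For `"generate"`, the manifest path; for `"phantom-qc"`, the QC table.
#' @export
run_pipeline <- function(config = cohort_config(),
                         mode = c("full", "generate", "analyse", "phantom-qc"),
                         outdir = NULL,
                         cohort_dir = NULL,
                         smooth_sd_mm = 0,
                         segmentation = c("mask", "threshold"),
                         phantom = phantom_spec(),
                         n_sessions = 20L,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  segmentation <- match.arg(segmentation)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }

  if (mode == "phantom-qc") {
    qc <- stage("phantom-qc",
                phantom_qc(phantom, n_sessions, seed = config$seed))
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(qc, file.path(outdir, "phantom_qc.csv"),
                       row.names = FALSE)
    }
    return(qc)
  }

  if (mode == "generate") {
    if (is.null(cohort_dir)) stop("generate mode requires `cohort_dir`")
    cohort <- stage("generate", generate_cohort(config))
    path <- stage("write", write_cohort(cohort, cohort_dir))
    return(invisible(path))
  }

  cohort <- if (mode == "analyse") {
    if (is.null(cohort_dir) ||
        !file.exists(file.path(cohort_dir, "manifest.csv")))
      stop("analyse mode requires a `cohort_dir` containing manifest.csv")
    stage("read", read_cohort(cohort_dir))
  } else {
    stage("generate", generate_cohort(config))
  }

  measures <- stage("quantify",
                    measure_cohort(cohort, smooth_sd_mm = smooth_sd_mm,
                                   segmentation = segmentation))
  excluded <- attr(measures, "excluded")
  if (nrow(excluded) > 0)
    say("[quantify] excluded %d subject(s): %s", nrow(excluded),
        paste(excluded$subject_id, collapse = ", "))
  measures <- stage("volume-correct", correct_measures(measures))
  models <- attr(measures, "correction_models")
  report_body <- stage("analyse", agreement_report(measures))

  report <- list(
    provenance = list(
      package = "airtrapr",
      version = as.character(utils::packageVersion("airtrapr")),
      seed = cohort$config$seed,
      config_hash = config_hash(unclass(cohort$config)),
      config = unclass(cohort$config),
      smooth_sd_mm = smooth_sd_mm,
      segmentation = segmentation,
      note = "volume-correction slopes estimated on the analysed cohort itself"),
    exclusions = list(n_excluded = nrow(excluded),
                      subjects = excluded$subject_id,
                      n_analysed = length(unique(measures$subject_id))),
    correction_models = lapply(models, function(m)
      m[c("measure", "covariate", "slope", "degenerate", "reference")]),
    measures = strip_points(report_body))
  class(report) <- "agreement_report"
  attr(report, "measures_table") <- measures
  attr(report, "summary_table") <- report_summary_table(report_body)
  attr(report, "points_table") <- report_points_table(report_body)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage("report", {
      write_json_atomic(unclass(report), file.path(outdir, "report.json"))
      utils::write.csv(attr(report, "summary_table"),
                       file.path(outdir, "summary.csv"), row.names = FALSE)
      utils::write.csv(attr(report, "points_table"),
                       file.path(outdir, "bland_altman_points.csv"),
                       row.names = FALSE)
      m <- attr(report, "measures_table")
      attr(m, "correction_models") <- NULL
      attr(m, "excluded") <- NULL
      utils::write.csv(m, file.path(outdir, "measures.csv"), row.names = FALSE)
    })
  }
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d subjects analysed, %d excluded (seed %d)\n",
              x$exclusions$n_analysed, x$exclusions$n_excluded,
              x$provenance$seed))
  for (meas in names(x$measures)) {
    m <- x$measures[[meas]]
    cat(sprintf("  %s: mean diff %.2f, LoA %.2f to %.2f, ccc %.3f\n",
                meas, m$uncorrected$mean_diff, m$uncorrected$loa_low,
                m$uncorrected$loa_high, m$uncorrected$ccc))
    cat(sprintf("    volume-corrected LoA %.2f to %.2f (Sandvik-Olsson p = %.3f)\n",
                m$volume_corrected$loa_low, m$volume_corrected$loa_high,
                m$tests$volume_correction$p))
    cat(sprintf("    subgroups inferior n=%d LoA %.2f to %.2f / superior n=%d LoA %.2f to %.2f (Levene p = %.3f)\n",
                m$subgroup_n$inferior, m$inferior$loa_low, m$inferior$loa_high,
                m$subgroup_n$superior, m$superior$loa_low, m$superior$loa_high,
                m$tests$subgroup$p))
  }
  invisible(x)
}
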