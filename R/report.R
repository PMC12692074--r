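# Pipeline orchestration: simulate -> measure -> analyze, with structured
# JSON-lines logging.  The CLI script in inst/cli/ is a thin wrapper over
# these functions.

log_line <- function(path, event, ...) {
  if (is.null(path)) return(invisible())
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                package_version = as.character(utils::packageVersion("lumbalign")),
                event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10), "\n",
      file = path, append = TRUE, sep = "")
  invisible()
}

#' Simulate a cohort to disk
#'
#' Generates a two-group landmark cohort from a spec (or the bundled
#' reference preset) and writes `landmarks.csv` (long format) and
#' `truth.csv` plus a JSON-lines run log.
#'
#' @param spec a [cohort_spec()], or `NULL` to use
#'   [reference_cohort_spec()] with `n` and `seed`.
#' @param out_dir output directory (created if needed).
#' @param n,seed,noise_sd used only when `spec` is `NULL`.
#' @return invisibly, a list with the output paths and the truth table.
#' @export
run_simulate <- function(spec = NULL, out_dir, n = 50L, seed = NULL,
                         noise_sd = 0.55) {
  if (is.null(spec)) {
    if (is.null(seed)) stop("a seed is required to simulate", call. = FALSE)
    spec <- reference_cohort_spec(n = n, seed = seed, noise_sd = noise_sd)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  log_line(log_path, "simulate_start", seed = spec$seed, n = spec$n,
           noise_sd = spec$noise_sd,
           antithetic = spec$antithetic)
  coh <- generate_cohorts(spec)
  lm_path <- file.path(out_dir, "landmarks.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_landmarks(c(coh$normal, coh$albp), lm_path)
  utils::write.csv(coh$truth, truth_path, row.names = FALSE, quote = FALSE)
  log_line(log_path, "simulate_done", landmarks = lm_path, truth = truth_path,
           subjects = 2L * spec$n)
  invisible(list(landmarks = lm_path, truth = truth_path,
                 truth_table = coh$truth, log = log_path))
}

#' Measure a landmark CSV
#'
#' Reads a long-format landmark CSV, measures every complete subject, skips
#' (and logs) incomplete ones, and writes the wide measurement CSV.  A
#' subject missing only decorative points (the pubis feeds no angle) is still
#' measured; fields whose landmarks are absent come out `NA`.
#'
#' @param landmarks_csv input path.
#' @param out_csv output path for the measurement table.
#' @param ellipse fit the lordosis ellipse per subject (default `TRUE`).
#' @param log_path optional JSON-lines log file.
#' @return invisibly, the measurement data.frame (also written to
#'   `out_csv`).
#' @export
run_measure <- function(landmarks_csv, out_csv, ellipse = TRUE,
                        log_path = NULL) {
  sets <- read_landmarks(landmarks_csv)
  if (!length(sets)) stop("no subjects in ", landmarks_csv, call. = FALSE)
  incomplete <- vapply(sets, function(s) !s$complete, logical(1L))
  for (s in sets[incomplete])
    log_line(log_path, "incomplete_subject", subject = s$subject_id,
             points = nrow(s$points))
  rec <- measure_cohort(sets, ellipse = ellipse)
  write_measurements(rec, out_csv)
  log_line(log_path, "measure_done", subjects = nrow(rec), out = out_csv)
  invisible(rec)
}

#' Analyze a two-group measurement table
#'
#' The full statistical battery: per-group descriptives with t-tests,
#' normality flags, Spearman correlation matrices per group, empirical ROC
#' per variable (fixed orientation: higher value predicts ALBP), and -- for
#' variables whose t-test is significant at `alpha` -- Cohen's d with the
#' noncentral-t required sample size.
#'
#' @param measurements a data.frame or a path to a wide measurement CSV.
#' @param out_dir optional output directory for `report.json` and the CSV
#'   tables.
#' @param alpha significance level for the effect-size follow-up.
#' @param power target power of the sample-size calculation.
#' @param variables measurement variables to analyze; defaults to the
#'   standard set present in the data.
#' @param plots write dotplot/ROC pdf figures into `out_dir`.
#' @return object of class `alignment_report` (list of the component
#'   results).
#' @export
run_analyze <- function(measurements, out_dir = NULL, alpha = 0.05,
                        power = 0.80, variables = NULL, plots = FALSE) {
  df <- if (is.character(measurements)) read_measurements(measurements)
  else measurements
  if (!"group" %in% names(df))
    stop("measurement table has no group column", call. = FALSE)
  groups <- setdiff(unique(df$group), "unknown")
  if (length(groups) < 2L)
    stop("analysis needs two groups, got ",
         paste(unique(df$group), collapse = ", "), call. = FALSE)
  df <- df[df$group %in% groups[1:2], ]
  # reference group first (normal before albp when present)
  ref_first <- intersect(c("normal", "albp"), groups)
  if (length(ref_first) == 2L) groups <- ref_first
  if (is.null(variables))
    variables <- intersect(MEASUREMENT_VARS, names(df))
  variables <- variables[vapply(variables, function(v)
    sum(is.finite(df[[v]])) > 3L, logical(1L))]

  summary_tab <- describe_groups(df[, c("group", variables)],
                                 variables = variables)
  norm_flags <- normality_flags(df, variables)
  correlations <- lapply(stats::setNames(groups, groups), function(g) {
    sub <- df[df$group == g, ]
    vv <- variables[vapply(variables, function(v)
      stats::sd(sub[[v]], na.rm = TRUE) > 0, logical(1L))]
    spearman_matrix(sub, vv)
  })
  roc <- lapply(stats::setNames(variables, variables), function(v) {
    roc_analysis(df[[v]][df$group == groups[1L]],
                 df[[v]][df$group == groups[2L]])
  })
  roc_tab <- data.frame(
    variable = variables,
    auc = vapply(roc, `[[`, 0, "auc"),
    cutoff = round(vapply(roc, `[[`, 0, "optimal_cutoff"), 1L),
    sensitivity = vapply(roc, `[[`, 0, "sens_at_cutoff"),
    specificity = vapply(roc, `[[`, 0, "spec_at_cutoff"),
    youden_j = vapply(roc, `[[`, 0, "youden_j"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  sig <- summary_tab$variable[!is.na(summary_tab$p_value) &
                                summary_tab$p_value < alpha]
  effects <- lapply(stats::setNames(sig, sig), function(v) {
    r <- summary_tab[summary_tab$variable == v, ]
    es <- cohens_d(r[[paste0(groups[1L], "_mean")]],
                   r[[paste0(groups[1L], "_sd")]],
                   r[[paste0(groups[1L], "_n")]],
                   r[[paste0(groups[2L], "_mean")]],
                   r[[paste0(groups[2L], "_sd")]],
                   r[[paste0(groups[2L], "_n")]])
    list(d = es$d, pooled_sd = es$pooled_sd,
         n_per_group = required_sample_size(es$d, alpha = alpha,
                                            power = power))
  })

  rep <- structure(
    list(groups = groups, summary = summary_tab, normality = norm_flags,
         correlations = correlations, roc = roc, roc_table = roc_tab,
         effects = effects, alpha = alpha, power = power),
    class = "alignment_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(out_dir, "log.jsonl")
    utils::write.csv(as.data.frame(summary_tab),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(roc_tab, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    for (g in groups)
      utils::write.csv(round(correlations[[g]]$rho, 3L),
                       file.path(out_dir, paste0("spearman_", g, ".csv")))
    json <- list(
      groups = groups,
      summary = as.data.frame(summary_tab),
      roc = roc_tab,
      effects = effects,
      normality = norm_flags,
      alpha = alpha, power = power
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
    log_line(log_path, "analyze_done", variables = length(variables),
             significant = sig)
    if (plots) {
      grDevices::pdf(file.path(out_dir, "roc_curves.pdf"), width = 6,
                     height = 6)
      for (v in variables) plot(roc[[v]], main = v)
      grDevices::dev.off()
      grDevices::pdf(file.path(out_dir, "dotplots.pdf"), width = 7,
                     height = 4)
      for (v in variables) {
        graphics::stripchart(df[[v]] ~ factor(df$group, levels = groups),
                             method = "jitter", pch = 1, vertical = FALSE,
                             xlab = v, main = v)
      }
      grDevices::dev.off()
    }
  }
  rep
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("Sagittal alignment analysis:",
      paste(x$groups, collapse = " vs "), "\n\n")
  print(x$summary)
  cat("\nROC (value >= cutoff predicts", x$groups[2L], "):\n")
  print(format(x$roc_table, digits = 3L), row.names = FALSE)
  if (length(x$effects)) {
    cat("\nEffect sizes for significant variables (alpha =", x$alpha, "):\n")
    for (v in names(x$effects))
      cat(sprintf("  %s: d = %.3f, required n = %d/group (power %.2f)\n",
                  v, x$effects[[v]]$d, x$effects[[v]]$n_per_group, x$power))
  }
  invisible(x)
}
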