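# Cohort arm: group summaries, pairwise comparisons and end-to-end
# orchestration of the three analysis arms.

#' Summarize one group's per-sample metric values
#'
#' Mean, sample SD (n - 1; 0 by convention for n = 1), median and the 5th
#' and 95th percentiles (linear interpolation between order statistics), the
#' quantities plotted as box-whisker summaries.
#'
#' @param values numeric vector of per-sample values.
#' @param group group label.
#' @param metric metric name carried into the output.
#' @return one-row data.frame: group, metric, n, mean, sd, median, p5, p95.
#' @export
summarize_group <- function(values, group, metric = "metric") {
  values <- values[is.finite(values)]
  if (length(values) == 0) mf_stop("empty group", "empty_group")
  n <- length(values)
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  data.frame(group = group, metric = metric, n = n,
             mean = mean(values),
             sd = if (n > 1) stats::sd(values) else 0,
             median = q[2], p5 = q[1], p95 = q[3])
}

#' Two-sample pooled-variance t-test between groups
#'
#' Student's two-sided t-test with pooled variance. The degenerate case of
#' zero pooled variance with equal means returns t = 0, p = 1 by convention.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param group_a,group_b labels carried into the output.
#' @return one-row data.frame: group_a, group_b, t_statistic, df, p_value,
#'   significant (at alpha = 0.05).
#' @export
two_sample_ttest <- function(a, b, group_a = "a", group_b = "b") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    mf_stop("both groups need at least two samples", "insufficient_n")
  }
  res <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {
    # constant data: zero pooled variance
    if (mean(a) == mean(b)) {
      tt <- 0; p <- 1
    } else {
      tt <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
    df <- length(a) + length(b) - 2
  } else {
    tt <- unname(res$statistic); p <- res$p.value; df <- unname(res$parameter)
  }
  data.frame(group_a = group_a, group_b = group_b, t_statistic = tt,
             df = df, p_value = p, significant = p < 0.05)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with significance from the t transform on n - 2 degrees
#' of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    mf_stop("need equal-length vectors with n >= 3", "invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    mf_stop("correlation undefined for zero-variance input",
            "undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Run the full multifunctional pipeline on a synthetic cohort
#'
#' For every subject: generate the configured phantoms, run the elastography
#' arm (per axis, averaged), the structural arm (OCTSS) and the angiography
#' arm (lumen diameter), then aggregate per group and run all pairwise
#' pooled t-tests per metric. Subjects are generated and analysed one at a
#' time to bound memory.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for the cohort draw.
#' @param out_dir if non-`NULL`, writes `metrics.csv`, `summaries.csv` and
#'   `comparisons.csv` there.
#' @return list of class `pipeline_result`: `metrics` (per-subject
#'   data.frame), `summaries`, `comparisons`, `truths`.
#' @export
run_pipeline <- function(config, seed, out_dir = NULL) {
  truths <- draw_cohort_truths(config, seed)
  metrics <- truths
  metrics$wave_speed_mps <- NA_real_
  metrics$octss_db_per_mm <- NA_real_
  metrics$lumen_diameter_um <- NA_real_
  for (i in seq_len(nrow(truths))) {
    ph <- make_subject_phantoms(truths[i, ], config)
    if (!is.null(ph$oce)) {
      fits <- lapply(ph$oce, function(mb) {
        tryCatch(oce_pipeline(mb), mfoct_error = function(e) NULL)
      })
      fits <- Filter(Negate(is.null), fits)
      if (length(fits) > 0) {
        metrics$wave_speed_mps[i] <- average_axes(fits)
      } else {
        mf_warn(sprintf("subject %d: no valid OCE axis; skipped", i),
                "subject_skipped")
      }
    }
    if (!is.null(ph$structural)) {
      res <- tryCatch(octss_pipeline(ph$structural),
                      mfoct_error = function(e) NULL)
      if (!is.null(res)) metrics$octss_db_per_mm[i] <- res$mean_slope
    }
    if (!is.null(ph$octa)) {
      res <- tryCatch(suppressWarnings(
        octa_pipeline(ph$octa, noise_rows = 8L)),
        mfoct_error = function(e) NULL)
      if (!is.null(res) && !is.null(res$vessel)) {
        metrics$lumen_diameter_um[i] <- res$vessel$lumen_diameter_um
      }
    }
  }
  metric_cols <- c(wave_speed_mps = "wave_speed_mps",
                   octss_db_per_mm = "octss_db_per_mm",
                   lumen_um = "lumen_diameter_um")
  groups <- unique(metrics$group)
  summaries <- list(); comparisons <- list()
  for (m in names(metric_cols)) {
    col <- metric_cols[[m]]
    vals <- split(metrics[[col]], metrics$group)
    vals <- lapply(vals, function(v) v[is.finite(v)])
    have <- names(vals)[vapply(vals, length, integer(1)) > 0]
    for (g in have) {
      summaries[[length(summaries) + 1L]] <- summarize_group(vals[[g]], g, m)
    }
    if (length(have) >= 2) {
      cmb <- utils::combn(have, 2)
      for (k in seq_len(ncol(cmb))) {
        ga <- cmb[1, k]; gb <- cmb[2, k]
        if (length(vals[[ga]]) >= 2 && length(vals[[gb]]) >= 2) {
          row <- two_sample_ttest(vals[[ga]], vals[[gb]], ga, gb)
          row$metric <- m
          comparisons[[length(comparisons) + 1L]] <- row
        }
      }
    }
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else NULL
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL
  out <- structure(list(metrics = metrics, summaries = summaries,
                        comparisons = comparisons, truths = truths),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(summaries)) {
      utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                       row.names = FALSE)
    }
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  if (!is.null(x$summaries)) {
    cat("summaries:\n"); print(x$summaries, row.names = FALSE)
  }
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n"); print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
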