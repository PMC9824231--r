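#' Clinical reference for angular measurement error
#'
#' Published human goniometry error in the clinical environment,
#' 12.78 +/- 7.44 degrees, used to band sensor accuracy, with the 5-degree
#' margin that separates a moderate from a poor rating.
#'
#' @param mean,sd Reference error mean and SD in degrees.
#' @param moderate_margin Degrees above the reference mean still rated
#'   moderate.
#' @return An object of class `clinical_reference`.
#' @export
clinical_reference <- function(mean = 12.78, sd = 7.44, moderate_margin = 5) {
  structure(list(mean = mean, sd = sd, moderate_margin = moderate_margin),
            class = "clinical_reference")
}

#' Per-sample absolute error between a sensor and the gold standard
#'
#' @param sensor,gold Aligned angle series (or numeric vectors) of equal
#'   length.
#' @return Numeric vector of `|sensor - gold|` in degrees.
#' @export
absolute_error <- function(sensor, gold) {
  s <- series_values(sensor); g <- series_values(gold)
  if (length(s) != length(g)) {
    kv_stop("kv_length_mismatch", "series of length %d and %d are not aligned",
            length(s), length(g))
  }
  abs(s - g)
}

#' Root mean square of an error series
#'
#' `sqrt(mean(x^2))` — the dispersion summary reported alongside the median
#' absolute error.
#'
#' @param errors Non-empty numeric vector.
#' @return RMS in the units of `errors`.
#' @export
rms_error <- function(errors) {
  errors <- series_values(errors)
  if (length(errors) == 0) kv_stop("kv_empty_series", "cannot take the RMS of nothing")
  sqrt(mean(errors^2))
}

#' Classify a median error against the clinical reference
#'
#' Ratings follow the clinical-reference rule: *excellent* when the median
#' error plus its SD stays below the reference mean; *good* when the median
#' alone is below it; *moderate* when the median exceeds it by at most the
#' moderate margin (5 degrees); *poor* beyond that. The moderate band is
#' judged on the median alone, not median + SD.
#'
#' @param median_error Median absolute error in degrees (>= 0).
#' @param sd_error Its standard deviation in degrees (>= 0).
#' @param ref A [clinical_reference()].
#' @return Ordered factor with levels poor < moderate < good < excellent.
#' @export
classify_error <- function(median_error, sd_error, ref = clinical_reference()) {
  stopifnot(median_error >= 0, sd_error >= 0)
  label <- if (median_error + sd_error < ref$mean) "excellent"
  else if (median_error < ref$mean) "good"
  else if (median_error <= ref$mean + ref$moderate_margin) "moderate"
  else "poor"
  factor(label, levels = c("poor", "moderate", "good", "excellent"), ordered = TRUE)
}

#' Correlation strength band
#'
#' The Portney–Watkins bands for a Pearson coefficient: poor (< 0.5),
#' moderate (0.5 to < 0.75), good (0.75 to < 0.9), excellent (>= 0.9).
#'
#' @param r Pearson correlation coefficient.
#' @return Ordered factor with levels poor < moderate < good < excellent.
#' @export
correlation_band <- function(r) {
  label <- ifelse(r < 0.5, "poor",
           ifelse(r < 0.75, "moderate",
           ifelse(r < 0.9, "good", "excellent")))
  factor(label, levels = c("poor", "moderate", "good", "excellent"), ordered = TRUE)
}

#' Pearson correlation with its strength band
#'
#' Correlates the synchronized angular values of a sensor stream with the
#' gold standard (the correlation is taken on the angle series themselves,
#' not on error series).
#'
#' @param sensor,gold Aligned angle series or numeric vectors.
#' @return List with elements `r` and `band`.
#' @export
pearson_band <- function(sensor, gold) {
  s <- series_values(sensor); g <- series_values(gold)
  if (length(s) != length(g)) {
    kv_stop("kv_length_mismatch", "series of length %d and %d are not aligned",
            length(s), length(g))
  }
  if (sd(s) < 1e-12 || sd(g) < 1e-12) {
    kv_stop("kv_zero_variance", "correlation undefined for a constant series")
  }
  r <- cor(s, g)
  list(r = r, band = correlation_band(r))
}

#' Significance tier for a p-value
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.001, `""` otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", ""))
}

#' Nonparametric rank comparisons across sensors
#'
#' Friedman's rank-sum test across all sensors, with paired Wilcoxon
#' signed-rank tests between each sensor pair as the post hoc analysis,
#' blocked on movement executions. A normality pre-check (Shapiro–Wilk on
#' the pooled errors) records why the nonparametric path applies.
#'
#' @param errors A numeric matrix of paired error summaries: one row per
#'   execution (block), one column per sensor; at least 3 sensors.
#' @return List with `normality_p`, `friedman` (statistic, p.value, tier)
#'   and `pairwise` (data frame: sensor_a, sensor_b, p.value, tier).
#' @export
rank_tests <- function(errors) {
  errors <- as.matrix(errors)
  if (ncol(errors) < 3) {
    kv_stop("kv_bad_groups", "Friedman's test needs at least 3 paired groups")
  }
  if (anyNA(errors)) kv_stop("kv_bad_groups", "paired groups must be complete")
  if (is.null(colnames(errors))) colnames(errors) <- paste0("sensor", seq_len(ncol(errors)))

  pooled <- as.numeric(errors)
  normality_p <- tryCatch(
    shapiro.test(if (length(pooled) > 5000) pooled[seq_len(5000)] else pooled)$p.value,
    error = function(e) NA_real_)

  fr <- friedman.test(errors)
  # fully tied blocks leave the statistic undefined: no rank differences
  if (is.nan(fr$statistic)) {
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(colnames(errors), 2)
  pw <- data.frame(
    sensor_a = pairs[1, ], sensor_b = pairs[2, ],
    p.value = apply(pairs, 2, function(pr) {
      suppressWarnings(
        wilcox.test(errors[, pr[1]], errors[, pr[2]], paired = TRUE,
                    exact = FALSE)$p.value)
    })
  )
  # identical paired samples: no information, not significance
  pw$p.value[is.nan(pw$p.value)] <- 1
  pw$tier <- significance_tier(pw$p.value)
  list(normality_p = normality_p,
       friedman = list(statistic = unname(fr$statistic),
                       p.value = fr$p.value,
                       tier = significance_tier(fr$p.value)),
       pairwise = pw)
}

#' Aggregate per-movement error summaries into group rows
#'
#' Reproduces the table-level aggregation convention of the validation
#' study: per limb group (upper/lower), the arithmetic mean and sample
#' (n-1) standard deviation of the per-movement values; the all-data row
#' pools the upper- and lower-limb per-movement values before averaging.
#' A single-movement group reports its value with `NA` for the SD.
#'
#' @param per_movement Data frame with columns `movement`, `limb`
#'   (`"upper"`/`"lower"`), `sensor`, and the value column.
#' @param value Name of the value column to aggregate (default
#'   `"median_ae"`).
#' @return Data frame with columns `sensor`, `group` (`upper`, `lower`,
#'   `all`), `n`, `mean`, `sd`.
#' @export
aggregate_report <- function(per_movement, value = "median_ae") {
  stopifnot(all(c("movement", "limb", "sensor", value) %in% names(per_movement)))
  if (nrow(per_movement) == 0) kv_stop("kv_empty_group", "nothing to aggregate")
  one <- function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_)
  }
  rows <- list()
  for (s in unique(per_movement$sensor)) {
    sub <- per_movement[per_movement$sensor == s, ]
    for (g in intersect(c("upper", "lower"), unique(sub$limb))) {
      rows[[length(rows) + 1]] <-
        cbind(sensor = s, group = g, one(sub[[value]][sub$limb == g]))
    }
    rows[[length(rows) + 1]] <- cbind(sensor = s, group = "all", one(sub[[value]]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
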