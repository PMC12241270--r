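#' Point regression metrics for paired predictions
#'
#' With errors `e = estimate - reference`: mean error `ME = mean(e)`,
#' `MAE = mean(|e|)`, `RMSE = sqrt(mean(e^2))`, `SD = sd(e)` (sample standard
#' deviation, n-1 denominator), and `R^2 = 1 - sum(e^2) / sum((ref - mean(ref))^2)`.
#' When all references are equal, `R^2` is undefined and reported as `NA`.
#'
#' @param estimates,references Numeric vectors of equal length (>= 2), mmHg.
#' @return A one-row tibble with `r2`, `rmse`, `mae`, `me`, `sd`.
#' @export
regression_metrics <- function(estimates, references) {
  check_pairs(estimates, references)
  e <- estimates - references
  ss_tot <- sum((references - mean(references))^2)
  tibble::tibble(
    r2 = if (ss_tot > 0) 1 - sum(e^2) / ss_tot else NA_real_,
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    me = mean(e),
    sd = sd(e)
  )
}

check_pairs <- function(estimates, references, min_n = 2L) {
  if (length(estimates) != length(references)) abort_input("estimates and references must have equal length.")
  if (length(estimates) < min_n) abort_input(sprintf("need at least %d pairs.", min_n))
  if (any(!is.finite(estimates)) || any(!is.finite(references))) abort_input("pairs must be finite.")
  invisible(TRUE)
}

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples index pairs with replacement (paired resampling), recomputes the
#' statistic `n_boot` times and returns the percentile interval. Resamples on
#' which the statistic is undefined (`NA`/`NaN`, e.g. zero reference variance
#' for R-squared) are redrawn, up to a capped number of retries.
#'
#' @param statistic Function of `(estimates, references)` returning one number.
#' @param estimates,references Paired numeric vectors.
#' @param n_boot Bootstrap iterations.
#' @param alpha Two-sided level (the interval is `(alpha/2, 1 - alpha/2)`).
#' @param seed Integer seed.
#' @param max_retries Cap on redraws for undefined resamples.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(statistic, estimates, references, n_boot = 1000L,
                         alpha = 0.05, seed = 0L, max_retries = 100L) {
  check_pairs(estimates, references)
  n <- length(estimates)
  stats <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (r in seq_len(max_retries + 1L)) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- statistic(estimates[idx], references[idx])
        if (is.finite(val)) return(val)
      }
      abort_input("bootstrap statistic undefined on every resample attempt.")
    }, numeric(1))
  })
  qs <- unname(quantile(stats, c(alpha / 2, 1 - alpha / 2), type = 7))
  c(lo = qs[1], hi = qs[2])
}

#' Regression metrics with bootstrap confidence intervals
#'
#' @inheritParams bootstrap_ci
#' @return A tibble with one row per metric (`r2`, `rmse`, `mae`, `me`, `sd`):
#'   point `value`, `lo`, `hi`, and the +/- `half_width` form in which such
#'   intervals are commonly printed.
#' @export
metric_set <- function(estimates, references, n_boot = 1000L, alpha = 0.05, seed = 0L) {
  point <- regression_metrics(estimates, references)
  fns <- list(
    r2 = function(e, r) regression_metrics(e, r)$r2,
    rmse = function(e, r) sqrt(mean((e - r)^2)),
    mae = function(e, r) mean(abs(e - r)),
    me = function(e, r) mean(e - r),
    sd = function(e, r) sd(e - r)
  )
  rows <- purrr::imap(fns, function(fn, nm) {
    ci <- bootstrap_ci(fn, estimates, references, n_boot, alpha, seed = derive_seed(seed, match(nm, names(fns))))
    tibble::tibble(metric = nm, value = point[[nm]], lo = ci[["lo"]], hi = ci[["hi"]],
                   half_width = (ci[["hi"]] - ci[["lo"]]) / 2)
  })
  dplyr::bind_rows(rows)
}

#' Bland--Altman agreement analysis
#'
#' Differences `d = estimate - reference`; bias is `mean(d)` and the limits of
#' agreement are `bias +/- loa_multiplier * sd(d)`. Confidence intervals for
#' the bias and both limits use the same paired bootstrap as [bootstrap_ci()].
#'
#' @inheritParams bootstrap_ci
#' @param loa_multiplier Multiplier on `sd(d)` for the limits of agreement.
#' @return A list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   tibble `ci` (one row each for bias/loa_low/loa_high) and the differences.
#' @export
bland_altman <- function(estimates, references, loa_multiplier = 1.96,
                         n_boot = 1000L, alpha = 0.05, seed = 0L) {
  check_pairs(estimates, references)
  d <- estimates - references
  bias <- mean(d)
  s <- sd(d)
  fns <- list(
    bias = function(e, r) mean(e - r),
    loa_low = function(e, r) mean(e - r) - loa_multiplier * sd(e - r),
    loa_high = function(e, r) mean(e - r) + loa_multiplier * sd(e - r)
  )
  ci <- dplyr::bind_rows(purrr::imap(fns, function(fn, nm) {
    v <- bootstrap_ci(fn, estimates, references, n_boot, alpha, seed = derive_seed(seed, 10L + match(nm, names(fns))))
    tibble::tibble(quantity = nm, lo = v[["lo"]], hi = v[["hi"]])
  }))
  structure(
    list(bias = bias, loa_low = bias - loa_multiplier * s,
         loa_high = bias + loa_multiplier * s, sd = s, ci = ci,
         means = (estimates + references) / 2, diffs = d),
    class = "bland_altman"
  )
}

#' Cumulative percentage of absolute errors within thresholds
#'
#' @param estimates,references Paired numeric vectors (mmHg).
#' @param thresholds Thresholds in mmHg (inclusive comparison).
#' @return Named numeric vector of percentages, one per threshold.
#' @export
cumulative_within <- function(estimates, references, thresholds = c(5, 10, 15)) {
  if (length(estimates) < 1) abort_input("need at least one pair.")
  check_pairs(estimates, references, min_n = 1L)
  ae <- abs(estimates - references)
  stats::setNames(vapply(thresholds, function(t) 100 * mean(ae <= t), numeric(1)),
                  paste0("within_", thresholds))
}

#' BHS grade from cumulative error percentages
#'
#' A grade requires all three of its thresholds to be met:
#' A = (>= 60, >= 85, >= 95), B = (>= 50, >= 75, >= 90), C = (>= 40, >= 65, >= 85)
#' percent of absolute errors within 5, 10 and 15 mmHg; otherwise D.
#'
#' @param percentages Numeric vector of three percentages (within 5, 10,
#'   15 mmHg).
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
bhs_grade <- function(percentages) {
  if (length(percentages) != 3 || any(!is.finite(percentages)) ||
      any(percentages < 0) || any(percentages > 100) || is.unsorted(percentages)) {
    abort_input("`percentages` must be three non-decreasing values in [0, 100].")
  }
  bands <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  for (g in names(bands)) {
    if (all(percentages >= bands[[g]])) return(g)
  }
  "D"
}

#' AAMI compliance check
#'
#' Passes when `|ME| <= 5` mmHg and `SD <= 8` mmHg (inclusive).
#'
#' @param me Mean error (mmHg).
#' @param sd Standard deviation of the error (mmHg).
#' @return A one-row tibble with `me`, `sd`, `passes`.
#' @export
aami_check <- function(me, sd) {
  if (!is.finite(me) || !is.finite(sd)) abort_input("`me` and `sd` must be finite.")
  tibble::tibble(me = me, sd = sd, passes = abs(me) <= 5 && sd <= 8)
}

#' Percent improvement between two metric values
#'
#' `"higher_better"` (e.g. R-squared): `100 * (improved - baseline) / baseline`;
#' `"lower_better"` (e.g. RMSE, MAE): `100 * (baseline - improved) / baseline`.
#' The full-precision value is returned; round only for display.
#'
#' @param baseline,improved Metric values (baseline non-zero).
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @return Percent improvement (positive = improvement), or `NA` with a
#'   warning for a zero baseline.
#' @export
percent_improvement <- function(baseline, improved,
                                orientation = c("higher_better", "lower_better")) {
  orientation <- match.arg(orientation)
  if (!is.finite(baseline) || !is.finite(improved)) abort_input("inputs must be finite.")
  if (baseline == 0) {
    warn("zero baseline: percent improvement undefined.")
    return(NA_real_)
  }
  if (orientation == "higher_better") 100 * (improved - baseline) / baseline
  else 100 * (baseline - improved) / baseline
}

#' Full evaluation report for pooled predictions
#'
#' Assembles, for SBP and DBP: the five regression metrics with bootstrap
#' confidence intervals, Bland--Altman bias and limits of agreement with
#' intervals, cumulative error percentages with the BHS grade, and the AAMI
#' verdict.
#'
#' @param predictions Tibble with columns `sbp`, `dbp` (references) and
#'   `sbp_hat`, `dbp_hat` (estimates), e.g. `tidy()` of a [kfold_evaluate()]
#'   result.
#' @param n_boot,alpha,seed Bootstrap settings.
#' @return An object of class `bp_report` (named list with one entry per
#'   target, plus `n`).
#' @export
evaluate_report <- function(predictions, n_boot = 1000L, alpha = 0.05, seed = 0L) {
  needed <- c("sbp", "dbp", "sbp_hat", "dbp_hat")
  if (!all(needed %in% names(predictions))) {
    abort_input(sprintf("`predictions` must have columns: %s.", paste(needed, collapse = ", ")))
  }
  if (nrow(predictions) < 2) abort_input("need at least 2 prediction pairs.")
  one_target <- function(est, ref, tseed) {
    met <- metric_set(est, ref, n_boot, alpha, seed = tseed)
    ba <- bland_altman(est, ref, 1.96, n_boot, alpha, seed = tseed)
    cw <- cumulative_within(est, ref)
    list(
      metrics = met,
      bland_altman = ba,
      bhs = list(percentages = cw, grade = bhs_grade(unname(cw))),
      aami = aami_check(met$value[met$metric == "me"], met$value[met$metric == "sd"])
    )
  }
  structure(
    list(
      sbp = one_target(predictions$sbp_hat, predictions$sbp, derive_seed(seed, 21L)),
      dbp = one_target(predictions$dbp_hat, predictions$dbp, derive_seed(seed, 22L)),
      n = nrow(predictions)
    ),
    class = "bp_report"
  )
}

#' Long metric table of a report
#'
#' @param x A `bp_report`.
#' @param ... Unused.
#' @return Tibble with `target`, `metric`, `value`, `lo`, `hi`, `half_width`.
#' @export
tidy.bp_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$sbp$metrics, target = "sbp", .before = 1),
    dplyr::mutate(x$dbp$metrics, target = "dbp", .before = 1)
  )
}

#' One row per target summarizing a report
#'
#' @param x A `bp_report`.
#' @param ... Unused.
#' @return Tibble with point metrics, BHS percentages/grade and AAMI verdict.
#' @export
glance.bp_report <- function(x, ...) {
  row <- function(t, nm) {
    m <- stats::setNames(t$metrics$value, t$metrics$metric)
    tibble::tibble(
      target = nm, r2 = m[["r2"]], rmse = m[["rmse"]], mae = m[["mae"]],
      me = m[["me"]], sd = m[["sd"]],
      bias = t$bland_altman$bias, loa_low = t$bland_altman$loa_low,
      loa_high = t$bland_altman$loa_high,
      within_5 = t$bhs$percentages[["within_5"]],
      within_10 = t$bhs$percentages[["within_10"]],
      within_15 = t$bhs$percentages[["within_15"]],
      bhs_grade = t$bhs$grade, aami_pass = t$aami$passes
    )
  }
  dplyr::bind_rows(row(x$sbp, "sbp"), row(x$dbp, "dbp"))
}

#' @export
print.bp_report <- function(x, ...) {
  cat(sprintf("Blood-pressure evaluation report (n = %d windows)\n", x$n))
  g <- glance(x)
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    cat(sprintf(
      "  %s: R2 %.3f  RMSE %.2f  MAE %.2f  ME %+.2f  SD %.2f mmHg | BHS %s (%.1f/%.1f/%.1f%%) | AAMI %s\n",
      toupper(r$target), r$r2, r$rmse, r$mae, r$me, r$sd, r$bhs_grade,
      r$within_5, r$within_10, r$within_15, if (r$aami_pass) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Write / read an evaluation report as JSON
#'
#' @param report A `bp_report`.
#' @param path Output path.
#' @return `path` (write) / a `bp_report` (read).
#' @export
write_report_json <- function(report, path) {
  ser <- function(t) list(
    metrics = t$metrics,
    bland_altman = list(bias = t$bland_altman$bias, loa_low = t$bland_altman$loa_low,
                        loa_high = t$bland_altman$loa_high, sd = t$bland_altman$sd,
                        ci = t$bland_altman$ci),
    bhs = list(percentages = as.list(t$bhs$percentages), grade = t$bhs$grade),
    aami = t$aami
  )
  jsonlite::write_json(list(sbp = ser(report$sbp), dbp = ser(report$dbp), n = report$n),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- function(t) list(
    metrics = tibble::as_tibble(t$metrics),
    bland_altman = structure(
      list(bias = t$bland_altman$bias, loa_low = t$bland_altman$loa_low,
           loa_high = t$bland_altman$loa_high, sd = t$bland_altman$sd,
           ci = tibble::as_tibble(t$bland_altman$ci), means = NULL, diffs = NULL),
      class = "bland_altman"),
    bhs = list(percentages = unlist(t$bhs$percentages), grade = t$bhs$grade),
    aami = tibble::as_tibble(t$aami)
  )
  structure(list(sbp = de(raw$sbp), dbp = de(raw$dbp), n = raw$n), class = "bp_report")
}

#' Bland--Altman plot for an evaluation report
#'
#' @param object A `bp_report` (built with the raw differences available,
#'   i.e. not read back from JSON).
#' @param target `"sbp"` or `"dbp"`.
#' @param ... Unused.
#' @return A ggplot: per-window difference against mean, with bias and limits
#'   of agreement.
#' @export
autoplot.bp_report <- function(object, target = c("sbp", "dbp"), ...) {
  target <- match.arg(target)
  ba <- object[[target]]$bland_altman
  if (is.null(ba$means)) abort_input("raw differences unavailable (report was read from JSON).")
  df <- tibble::tibble(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "darkgreen", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "grey40", linetype = "dashed") +
    ggplot2::labs(x = sprintf("mean of estimate and reference %s (mmHg)", toupper(target)),
                  y = "estimate - reference (mmHg)") +
    ggplot2::theme_minimal()
}
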