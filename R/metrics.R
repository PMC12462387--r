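# Detection-rate and cohort-stability metrics.
#
# 0/0 rates are never silently coerced to 0: they come back as NA with an
# "undefined" flag, and aggregations report how many values were excluded.

#' Compute detection rates from TP/FP/FN/TN counts
#'
#' sensitivity = tp/(tp+fn), precision = tp/(tp+fp), fpr = fp/(fp+tn),
#' fnr = fn/(tp+fn), specificity = 1 - fpr, f1 = harmonic mean of
#' precision and sensitivity. Any 0/0 yields NA and is listed in the
#' \code{undefined} field.
#'
#' @param outcome a \code{detection_outcome} (or list with tp, fp, fn, tn).
#' @return object of class \code{rate_set}.
#' @export
compute_rates <- function(outcome) {
  cnt <- unlist(outcome[c("tp", "fp", "fn", "tn")])
  if (any(is.na(cnt)) || any(cnt < 0)) stop("counts must be non-negative")
  tp <- cnt[["tp"]]; fp <- cnt[["fp"]]; fn <- cnt[["fn"]]; tn <- cnt[["tn"]]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  prec <- safe_div(tp, tp + fp)
  fpr <- safe_div(fp, fp + tn)
  fnr <- if (is.na(sens)) NA_real_ else 1 - sens
  spec <- if (is.na(fpr)) NA_real_ else 1 - fpr
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  rates <- list(sensitivity = sens, precision = prec, specificity = spec,
                fpr = fpr, fnr = fnr, f1 = f1)
  rates$undefined <- names(rates)[vapply(rates, function(v)
    is.numeric(v) && is.na(v), NA)]
  class(rates) <- "rate_set"
  rates
}

#' @export
print.rate_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf("sens=%s prec=%s spec=%s fpr=%s fnr=%s f1=%s\n",
              fmt(x$sensitivity), fmt(x$precision), fmt(x$specificity),
              fmt(x$fpr), fmt(x$fnr), fmt(x$f1)))
  invisible(x)
}

#' Stability statistics of a metric across region tasks
#'
#' Sample mean, sample variance, standard deviation, coefficient of
#' variation (std/mean) and RMSE. RMSE is measured against the ideal
#' score 1.0 (deviation-from-ideal); the sample variance is reported
#' alongside so both deviation notions are available.
#'
#' @param values numeric vector of per-task metric values; NA values
#'   (undefined rates) are excluded and counted.
#' @return object of class \code{stability_report}: list(mean, variance,
#'   std, cv, rmse, n, n_excluded).
#' @export
stability_stats <- function(values) {
  n_excl <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("stability_stats needs at least 2 defined values")
  m <- mean(v)
  va <- stats::var(v)
  s <- sqrt(va)
  out <- list(
    mean = m, variance = va, std = s,
    cv = if (m > 0) s / m else NA_real_,
    rmse = sqrt(mean((v - 1)^2)),
    n = length(v), n_excluded = n_excl
  )
  if (n_excl > 0) {
    message(n_excl, " undefined value(s) excluded from stability statistics")
  }
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "mean=%.4f var=%.5f sd=%.4f cv=%s rmse=%.4f (n=%d, %d excluded)\n",
    x$mean, x$variance, x$std,
    if (is.na(x$cv)) "undef" else sprintf("%.4f", x$cv),
    x$rmse, x$n, x$n_excluded))
  invisible(x)
}
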