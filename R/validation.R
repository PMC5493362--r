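#' Align predictions with lagged observations
#'
#' Pairs the prediction on day *t* with the observation on day *t + lag*
#' (exposure leads outcome: an air-pollution effect can appear on the same
#' day, lag 0, or on subsequent days).  Pairs with a missing member are
#' dropped and counted.
#'
#' @param predicted,observed Numeric vectors on the same date index.
#' @param lag Non-negative integer lag in days.
#' @return List with `x` (predictions), `y` (lagged observations),
#'   `n` (pairs kept) and `n_dropped` (pairs lost to missing values).
#' @export
lag_align <- function(predicted, observed, lag = 0L) {
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' must share one date index",
         call. = FALSE)
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 0L)
    stop("'lag' must be a non-negative integer", call. = FALSE)
  n_days <- length(predicted)
  if (lag >= n_days)
    stop("lag (", lag, ") must be smaller than the series length (",
         n_days, ")", call. = FALSE)
  x <- predicted[seq_len(n_days - lag)]
  y <- observed[seq_len(n_days - lag) + lag]
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], n = sum(keep), n_dropped = sum(!keep))
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; the two-sided p-value comes from the t
#' distribution with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs, each
#'   with nonzero variance).
#' @return Named vector `c(r, p)`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Dichotomize admission counts
#'
#' Labels a day positive (1) when its admission count exceeds the
#' threshold, else negative (0).  The default threshold of 2 treats days
#' with up to 2 admissions as the negative class.
#'
#' @param counts Non-negative counts.
#' @param threshold Integer cut; positive means `count > threshold`.
#' @return Integer vector of 0/1 labels.
#' @export
dichotomize <- function(counts, threshold = 2L) {
  if (any(!is.na(counts) & counts < 0))
    stop("'counts' must be non-negative", call. = FALSE)
  as.integer(counts > threshold)
}

#' ROC area under the curve with a Hanley-McNeil confidence interval
#'
#' AUC is the Mann-Whitney pair-counting estimator (concordant pairs count
#' 1, ties count 1/2), computed via midranks.  The 95 percent confidence
#' interval uses the Hanley-McNeil standard error
#' \deqn{SE^2 = \frac{A(1-A) + (n_1-1)(Q_1-A^2) + (n_0-1)(Q_2-A^2)}{n_1 n_0}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}, a normal quantile
#' of 1.96, and clamping to `[0, 1]`.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return List with `auc`, `ci95` (`c(low, high)`), `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))  # AUC 0.75
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("'labels' must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined ROC: need at least one positive and one negative label",
         call. = FALSE)
  ranks <- rank(scores, ties.method = "average")
  auc <- (sum(ranks[labels == 1L]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  list(auc = auc, ci95 = ci, n_pos = n_pos, n_neg = n_neg)
}

#' Lagged validation of model predictions against observed admissions
#'
#' For each lag, pairs predictions on day *t* with observed admissions on
#' day *t + lag*, then reports the Pearson correlation (with p-value) and
#' the ROC AUC of the predictions against dichotomized admissions, with a
#' Hanley-McNeil 95 percent confidence interval.
#'
#' @param predicted,observed Numeric vectors on the same date index.
#' @param lags Integer vector of lags in days (default `0:2`).
#' @param threshold Dichotomization cut passed to [dichotomize()].
#' @return A data frame of class `validation_report` with one row per lag:
#'   `lag`, `n`, `pearson_r`, `pearson_p`, `auc`, `auc_lo`, `auc_hi`.
#' @export
validate_predictions <- function(predicted, observed, lags = 0:2,
                                 threshold = 2L) {
  rows <- lapply(lags, function(lag) {
    al <- tryCatch(lag_align(predicted, observed, lag),
                   error = function(e) stop("lag ", lag, ": ",
                                            conditionMessage(e),
                                            call. = FALSE))
    pr <- tryCatch(pearson(al$x, al$y),
                   error = function(e) stop("lag ", lag, ": ",
                                            conditionMessage(e),
                                            call. = FALSE))
    roc <- tryCatch(roc_auc(al$x, dichotomize(al$y, threshold)),
                    error = function(e) stop("lag ", lag, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    data.frame(lag = lag, n = al$n, pearson_r = pr[["r"]],
               pearson_p = pr[["p"]], auc = roc$auc,
               auc_lo = roc$ci95[1], auc_hi = roc$ci95[2])
  })
  report <- do.call(rbind, rows)
  attr(report, "threshold") <- threshold
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, digits = 3L, ...) {
  cat("Lagged validation: predictions vs observed admissions",
      sprintf("(positive day = more than %d admissions)\n",
              attr(x, "threshold")))
  cat(format_validation_report(x, digits), sep = "\n")
  invisible(x)
}

# plain-text lag x metric table (shared by print and the CLI report writer)
format_validation_report <- function(x, digits = 3L) {
  hdr <- sprintf("%-6s %5s %9s %10s %7s %15s", "lag", "n", "r", "p",
                 "AUC", "95% CI")
  body <- vapply(seq_len(nrow(x)), function(i) {
    sprintf("%-6d %5d %9.*f %10.2g %7.*f  (%.*f, %.*f)",
            x$lag[i], x$n[i], digits, x$pearson_r[i], x$pearson_p[i],
            digits, x$auc[i], digits, x$auc_lo[i], digits, x$auc_hi[i])
  }, character(1))
  c(hdr, body)
}
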