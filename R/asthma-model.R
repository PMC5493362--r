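#' Default configuration of the admissions model
#'
#' Four input variables, each with a `good` and a `bad` term, and a
#' five-term output variable counting daily hospital admissions for asthma
#' and pneumonia.  Breakpoints are anchored to Brazilian / WHO regulatory
#' guide values and to the observed ranges of the study region (Sao Jose
#' dos Campos, 2007):
#'
#' * `pm10` on `[0, 120]` ug/m3 -- `good` (0, 0, 25, 50), `bad`
#'   (25, 50, 120, 120); concentrations above 50 ug/m3 denote degraded air.
#' * `o3` on `[0, 200]` ug/m3 -- `good` (0, 0, 80, 160), `bad`
#'   (80, 160, 200, 200); 160 ug/m3 is the CONAMA hourly guide value.
#' * `so2` on `[0, 30]` ug/m3 -- `good` (0, 0, 10, 20), `bad`
#'   (10, 20, 30, 30); 20 ug/m3 is the WHO daily guideline.
#' * `temp_apparent` on `[0, 30]` C -- `good` (12, 18, 30, 30), `bad`
#'   (0, 0, 12, 18); cold aggravates respiratory disease, so low apparent
#'   temperature is the adverse state.
#'
#' The output variable `admissions` spans `[0, 16]` daily admissions with
#' five overlapping terms: `very_low` (0, 0, 2, 4), `low` (2, 4, 4, 6),
#' `medium` (5, 8, 8, 11), `high` (10, 12, 12, 14) and `very_high`
#' (12, 14, 16, 16).
#'
#' Every breakpoint, universe and the severity map can be overridden.
#'
#' @param inputs Named list of input-variable descriptions; each element is
#'   a list with fields `universe` and one breakpoint vector per term.
#' @param output Named list of output-term breakpoint vectors (term order
#'   is the severity order).
#' @param output_universe Numeric `c(lo, hi)` for the output variable.
#' @param severity_map Character vector of output-term names indexed by the
#'   number of `bad` antecedents (position 1 = zero bad inputs); must be
#'   monotone non-decreasing in severity.
#' @return A list of class `asthma_config`.
#' @export
asthma_config <- function(
    inputs = list(
      pm10 = list(universe = c(0, 120),
                  good = c(0, 0, 25, 50), bad = c(25, 50, 120, 120)),
      o3 = list(universe = c(0, 200),
                good = c(0, 0, 80, 160), bad = c(80, 160, 200, 200)),
      so2 = list(universe = c(0, 30),
                 good = c(0, 0, 10, 20), bad = c(10, 20, 30, 30)),
      temp_apparent = list(universe = c(0, 30),
                           good = c(12, 18, 30, 30), bad = c(0, 0, 12, 18))
    ),
    output = list(
      very_low = c(0, 0, 2, 4),
      low = c(2, 4, 4, 6),
      medium = c(5, 8, 8, 11),
      high = c(10, 12, 12, 14),
      very_high = c(12, 14, 16, 16)
    ),
    output_universe = c(0, 16),
    severity_map = c("very_low", "low", "medium", "high", "very_high")) {
  if (length(output) != 5L)
    stop("the output variable must have exactly 5 terms", call. = FALSE)
  for (v in names(inputs)) {
    n_terms <- sum(names(inputs[[v]]) != "universe")
    if (n_terms != 2L)
      stop("input variable '", v, "' must have exactly 2 terms",
           call. = FALSE)
  }
  if (length(severity_map) != length(inputs) + 1L)
    stop("'severity_map' needs one output term per possible count of bad ",
         "antecedents (0..", length(inputs), ")", call. = FALSE)
  if (!all(severity_map %in% names(output)))
    stop("'severity_map' references unknown output term(s)", call. = FALSE)
  sev_idx <- match(severity_map, names(output))
  if (is.unsorted(sev_idx))
    stop("'severity_map' must be monotone non-decreasing in the count of ",
         "bad antecedents", call. = FALSE)
  structure(list(inputs = inputs, output = output,
                 output_universe = output_universe,
                 severity_map = severity_map),
            class = "asthma_config")
}

#' Enumerate the 16-rule base
#'
#' One rule per element of \{good, bad\}^4: the consequent is the severity
#' map evaluated at the number of `bad` antecedents, so by default zero bad
#' inputs predict `very_low` admissions, all four bad predict `very_high`,
#' and intermediate counts interpolate through `low`, `medium` and `high`.
#'
#' @param severity_map As in [asthma_config()].
#' @param input_names Names of the input variables, in rule order.
#' @return A list of `2^length(input_names)` [fuzzy_rule()] objects.
#' @export
asthma_rules <- function(severity_map = c("very_low", "low", "medium",
                                          "high", "very_high"),
                         input_names = c("pm10", "o3", "so2",
                                         "temp_apparent")) {
  if (length(severity_map) != length(input_names) + 1L)
    stop("'severity_map' must have length(input_names) + 1 entries",
         call. = FALSE)
  combos <- expand.grid(rep(list(c("good", "bad")), length(input_names)),
                        stringsAsFactors = FALSE)
  names(combos) <- input_names
  lapply(seq_len(nrow(combos)), function(i) {
    ant <- unlist(combos[i, , drop = TRUE])
    n_bad <- sum(ant == "bad")
    fuzzy_rule(ant, severity_map[n_bad + 1L])
  })
}

#' Build the admissions fuzzy inference system
#'
#' Instantiates a [fuzzy_system()] from an [asthma_config()]: four input
#' variables with `good`/`bad` terms, the five-term output variable and the
#' 16-rule base generated by [asthma_rules()].
#'
#' @param config An [asthma_config()].
#' @param resolution Output-universe discretisation (default 1001 points).
#' @return A [fuzzy_system()].
#' @examples
#' sys <- asthma_system()
#' length(sys$rules)          # 16
#' names(sys$output$terms)    # the five severity terms
#' @export
asthma_system <- function(config = asthma_config(), resolution = 1001L) {
  if (!inherits(config, "asthma_config"))
    stop("'config' must be an asthma_config object", call. = FALSE)
  inputs <- lapply(names(config$inputs), function(v) {
    vc <- config$inputs[[v]]
    term_names <- setdiff(names(vc), "universe")
    fuzzy_variable(v, vc$universe,
                   lapply(term_names, function(tn) mf_trapezoid(tn, vc[[tn]])))
  })
  output <- fuzzy_variable("admissions", config$output_universe,
                           lapply(names(config$output), function(tn)
                             mf_trapezoid(tn, config$output[[tn]])))
  rules <- asthma_rules(config$severity_map, names(config$inputs))
  fuzzy_system(inputs, output, rules, resolution = resolution)
}

#' Predict admissions for a single day
#'
#' Applies Mamdani inference to one day's exposures.  If the record lacks
#' an apparent temperature but carries ambient temperature and relative
#' humidity, the apparent temperature is computed on the fly.
#'
#' @param system A [fuzzy_system()], e.g. from [asthma_system()].
#' @param record Named list / one-row data frame with `pm10`, `o3`, `so2`
#'   and either `temp_apparent` or both `temp` and `rh`.
#' @return Predicted daily admissions (crisp, within the output universe).
#' @export
predict_day <- function(system, record) {
  record <- as.list(record)
  if (is.null(record$temp_apparent) || is.na(record$temp_apparent)) {
    if (is.null(record$temp) || is.null(record$rh) ||
        is.na(record$temp) || is.na(record$rh))
      stop("record needs 'temp_apparent' or both 'temp' and 'rh'",
           call. = FALSE)
    record$temp_apparent <- apparent_temperature(record$temp, record$rh)
  }
  needed <- names(system$inputs)
  vals <- vapply(needed, function(v) {
    x <- record[[v]]
    if (is.null(x) || is.na(x))
      stop("record is missing exposure '", v, "'", call. = FALSE)
    as.numeric(x)
  }, numeric(1))
  infer(system, vals)
}

#' Predict admissions for a daily series
#'
#' Element-wise [predict_day()], vectorised internally.  Days with missing
#' exposures are emitted as `NA` (never dropped silently) and their dates
#' are reported in a message.
#'
#' @param system A [fuzzy_system()].
#' @param series A [daily_series()] (or data frame with the same columns).
#' @return Data frame with columns `date` and `predicted`, preserving the
#'   input's date order.
#' @export
predict_series <- function(system, series) {
  series <- as.data.frame(series)
  n <- nrow(series)
  out <- data.frame(date = series$date,
                    predicted = rep(NA_real_, n))
  if (n == 0L) return(out)
  if (!"temp_apparent" %in% names(series))
    series$temp_apparent <- NA_real_
  if (all(c("temp", "rh") %in% names(series))) {
    can_derive <- is.na(series$temp_apparent) &
      !is.na(series$temp) & !is.na(series$rh)
    if (any(can_derive))
      series$temp_apparent[can_derive] <-
        apparent_temperature(series$temp[can_derive], series$rh[can_derive])
  }
  vars <- names(system$inputs)
  miss <- setdiff(vars, names(series))
  if (length(miss))
    stop("series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  complete <- Reduce(`&`, lapply(vars, function(v) !is.na(series[[v]])))
  if (any(!complete))
    message(sum(!complete), " day(s) skipped for missing exposures: ",
            paste(utils::head(series$date[!complete], 10L), collapse = ", "),
            if (sum(!complete) > 10L) ", ..." else "")
  if (any(complete))
    out$predicted[complete] <-
      infer_frame(system, series[complete, vars, drop = FALSE])
  out
}
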