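#' Specification of the synthetic daily-series generator
#'
#' Describes a synthetic year of exposures and admissions with the marginal
#' structure observed in Sao Jose dos Campos in 2007 and a planted,
#' lag-specific pollutant-to-admissions association.  Pollutants follow a
#' stationary Gaussian AR(1) process scaled to the target mean/sd and
#' truncated to the observed min/max; ambient temperature and relative
#' humidity are generated the same way and apparent temperature is derived
#' from them.  Admissions are Poisson with log rate
#' `beta0 + sum over pollutants and lags of beta * standardized lagged
#' exposure`, capped at `cap`.
#'
#' Default marginals (mean, sd, min, max): PM10 (26.0, 11.3, 8.0, 89.0),
#' O3 (91.0, 67.9, 17.0, 162.0), SO2 (3.8, 3.3, 0.9, 27.0) ug/m3.
#' Ambient temperature (18, 2.5, 10, 28) C and humidity (75, 10, 40, 100)
#' percent are chosen so the derived apparent temperature has mean near
#' 17.9 C and stays within the observed 5.7-20.2 C spread.  The default
#' association plants `beta = 0.3` per SD of PM10 at lag 1; `beta0` is
#' `log(4.9)`, the observed mean daily admissions, and counts are capped at
#' the observed maximum of 16.
#'
#' @param n_days Number of days (>= 30; default 365).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param marginals Named list of `c(mean, sd, min, max)` per series.
#' @param rho AR(1) autocorrelation in `[0, 1)` shared by all series;
#'   default 0.5, a typical day-to-day persistence of urban pollutant
#'   levels.
#' @param beta Named list of per-pollutant lag-coefficient vectors (index 1
#'   = lag 0), on the log-rate scale per SD of exposure.
#' @param beta0 Baseline log rate.
#' @param cap Upper cap for the admission counts.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(
    n_days = 365L,
    seed = 1L,
    marginals = list(
      pm10 = c(mean = 26.0, sd = 11.3, min = 8.0, max = 89.0),
      o3 = c(mean = 91.0, sd = 67.9, min = 17.0, max = 162.0),
      so2 = c(mean = 3.8, sd = 3.3, min = 0.9, max = 27.0),
      temp = c(mean = 18.0, sd = 2.5, min = 10.0, max = 28.0),
      rh = c(mean = 75.0, sd = 10.0, min = 40.0, max = 100.0)
    ),
    rho = 0.5,
    beta = list(pm10 = c(0, 0.3, 0)),
    beta0 = log(4.9),
    cap = 16L) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 30L)
    stop("'n_days' must be an integer >= 30", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  for (v in names(marginals)) {
    m <- marginals[[v]]
    if (!all(c("mean", "sd", "min", "max") %in% names(m)))
      stop("marginal '", v, "' needs mean, sd, min and max", call. = FALSE)
    if (m[["sd"]] <= 0)
      stop("marginal '", v, "' must have sd > 0", call. = FALSE)
    if (m[["min"]] >= m[["max"]])
      stop("marginal '", v, "' has infeasible truncation bounds",
           call. = FALSE)
  }
  if (length(beta)) {
    unknown <- setdiff(names(beta), c("pm10", "o3", "so2"))
    if (length(unknown))
      stop("'beta' references non-pollutant series: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(n_days = n_days, seed = as.integer(seed),
                 marginals = marginals, rho = rho, beta = beta,
                 beta0 = beta0, cap = as.integer(cap),
                 start_date = as.Date("2007-01-01")),
            class = "generator_spec")
}

# stationary standard-normal AR(1) path of length n
ar1_path <- function(n, rho) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, sd = sqrt(1 - rho^2))
    for (t in 2:n) z[t] <- rho * z[t - 1L] + innov[t - 1L]
  }
  z
}

#' Generate synthetic daily exposures
#'
#' Draws one truncated-Gaussian AR(1) series per marginal in the spec and
#' derives the apparent temperature from ambient temperature and humidity.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A [daily_series()] with columns `date`, `pm10`, `o3`, `so2`,
#'   `temp`, `rh` and `temp_apparent` (no admissions).
#' @export
simulate_exposures <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  cols <- lapply(spec$marginals, function(m) {
    x <- m[["mean"]] + m[["sd"]] * ar1_path(spec$n_days, spec$rho)
    pmin(m[["max"]], pmax(m[["min"]], x))
  })
  df <- data.frame(date = spec$start_date + seq_len(spec$n_days) - 1L,
                   cols)
  df$temp_apparent <- apparent_temperature(df$temp, df$rh)
  daily_series(df)
}

#' Add synthetic admission counts to an exposure series
#'
#' Admissions on day *t* are Poisson with log rate
#' `beta0 + sum_p sum_lag beta[p][lag+1] * z[p, t-lag]` where `z` is the
#' exposure standardized by the spec's own marginal mean and sd (so each
#' beta is the log-rate change per SD of exposure).  Lagged values before
#' the start of the series contribute zero.  Counts are capped at
#' `spec$cap`.  Deterministic given `spec$seed` (a stream distinct from the
#' exposure stream).
#'
#' @param exposures A complete exposure [daily_series()].
#' @param spec A [generator_spec()].
#' @return The series with an `admissions` column appended.
#' @export
simulate_admissions <- function(exposures, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  df <- as.data.frame(exposures)
  n <- nrow(df)
  log_rate <- rep(spec$beta0, n)
  for (p in names(spec$beta)) {
    m <- spec$marginals[[p]]
    z <- (df[[p]] - m[["mean"]]) / m[["sd"]]
    bvec <- spec$beta[[p]]
    for (k in seq_along(bvec)) {
      lag <- k - 1L
      if (bvec[k] == 0) next
      z_lag <- c(rep(0, lag), z[seq_len(n - lag)])
      log_rate <- log_rate + bvec[k] * z_lag
    }
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed + 1L)
  df$admissions <- pmin(spec$cap, stats::rpois(n, exp(log_rate)))
  daily_series(df)
}

#' Generate a full synthetic daily series
#'
#' Convenience composition of [simulate_exposures()] and
#' [simulate_admissions()].
#'
#' @param spec A [generator_spec()].
#' @return A [daily_series()] with exposures and admissions.
#' @export
simulate_daily_series <- function(spec) {
  simulate_admissions(simulate_exposures(spec), spec)
}

#' Write a synthetic fixture to disk
#'
#' Writes the exposures-plus-admissions CSV (`<prefix>.csv`) and, for
#' provenance, the generating specification (`<prefix>_spec.yaml`) side by
#' side.
#'
#' @param spec A [generator_spec()].
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_fixture <- function(spec, prefix) {
  series <- simulate_daily_series(spec)
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  csv_path <- paste0(prefix, ".csv")
  spec_path <- paste0(prefix, "_spec.yaml")
  # drop the derived column so the CSV carries the 7 primary fields
  out <- as.data.frame(series)[, c("date", "pm10", "o3", "so2", "temp",
                                   "rh", "admissions")]
  write_daily_csv(out, csv_path)
  prov <- unclass(spec)
  prov$start_date <- format(prov$start_date, "%Y-%m-%d")
  prov$marginals <- lapply(prov$marginals, as.list)
  yaml::write_yaml(prov, spec_path, precision = 15L)
  invisible(c(csv = csv_path, spec = spec_path))
}
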