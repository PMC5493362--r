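#' Fuzzy IF-THEN rule
#'
#' A conjunctive (AND-only) rule joining one term per input variable to one
#' term of the output variable, e.g. *IF pm10 IS bad AND o3 IS good ...
#' THEN admissions IS medium*.
#'
#' @param antecedent Named character vector mapping input-variable names to
#'   term names; each variable may appear at most once.
#' @param consequent Output term name.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent) {
  if (!is.character(antecedent) || length(antecedent) == 0L ||
      is.null(names(antecedent)) || any(!nzchar(names(antecedent))))
    stop("'antecedent' must be a named character vector", call. = FALSE)
  if (anyDuplicated(names(antecedent)))
    stop("a rule may name each input variable at most once", call. = FALSE)
  if (!is.character(consequent) || length(consequent) != 1L)
    stop("'consequent' must be a single term name", call. = FALSE)
  structure(list(antecedent = antecedent, consequent = consequent),
            class = "fuzzy_rule")
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  cat("IF", paste(sprintf("%s IS %s", names(x$antecedent), x$antecedent),
                  collapse = " AND "),
      "THEN", x$consequent, "\n")
  invisible(x)
}

#' Mamdani fuzzy inference system
#'
#' Bundles input linguistic variables, one output variable, a rule base and
#' the discretisation resolution of the output universe.  Inference follows
#' the Mamdani scheme: rule activation by the minimum of antecedent
#' memberships, consequent truncation at the activation degree, pointwise
#' maximum aggregation across rules, and area-centre (centroid)
#' defuzzification.
#'
#' @param inputs List of [fuzzy_variable()] objects (the input variables).
#' @param output A single [fuzzy_variable()] (the output variable).
#' @param rules List of [fuzzy_rule()] objects.
#' @param resolution Number of evenly spaced discretisation points for the
#'   output universe; at least 101 (default 1001, at which the centroid
#'   discretisation error is far below 0.05 output units).
#' @return An object of class `fuzzy_system`.
#' @export
fuzzy_system <- function(inputs, output, rules, resolution = 1001L) {
  if (!is.list(inputs) || length(inputs) == 0L ||
      !all(vapply(inputs, inherits, logical(1), "fuzzy_variable")))
    stop("'inputs' must be a list of fuzzy_variable objects", call. = FALSE)
  if (!inherits(output, "fuzzy_variable"))
    stop("'output' must be a fuzzy_variable", call. = FALSE)
  if (!is.list(rules) || length(rules) == 0L ||
      !all(vapply(rules, inherits, logical(1), "fuzzy_rule")))
    stop("'rules' must be a non-empty list of fuzzy_rule objects",
         call. = FALSE)
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 101L)
    stop("'resolution' must be an integer >= 101", call. = FALSE)
  input_names <- vapply(inputs, `[[`, character(1), "name")
  if (anyDuplicated(input_names))
    stop("input variable names must be unique", call. = FALSE)
  names(inputs) <- input_names
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    unknown <- setdiff(names(r$antecedent), input_names)
    if (length(unknown))
      stop("rule ", i, " references unknown variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (v in names(r$antecedent)) {
      if (!r$antecedent[[v]] %in% names(inputs[[v]]$terms))
        stop("rule ", i, ": variable '", v, "' has no term '",
             r$antecedent[[v]], "'", call. = FALSE)
    }
    if (!r$consequent %in% names(output$terms))
      stop("rule ", i, ": consequent '", r$consequent,
           "' is not a term of the output variable", call. = FALSE)
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 resolution = resolution),
            class = "fuzzy_system")
}

#' @export
print.fuzzy_system <- function(x, ...) {
  cat(sprintf("<fuzzy_system> %d input variable(s), %d rule(s), output '%s' (%d terms), resolution %d\n",
              length(x$inputs), length(x$rules), x$output$name,
              length(x$output$terms), x$resolution))
  for (v in x$inputs) print(v)
  print(x$output)
  invisible(x)
}

#' Rule activation degree
#'
#' Returns the Mamdani firing strength of a rule: the minimum of the
#' membership degrees of its antecedent terms.
#'
#' @param rule A [fuzzy_rule()].
#' @param fuzzified Named list, one element per input variable, each a
#'   named vector of term degrees as returned by [fuzzify()].
#' @return A degree in `[0, 1]`.
#' @export
fire_strength <- function(rule, fuzzified) {
  stopifnot(inherits(rule, "fuzzy_rule"))
  missing_vars <- setdiff(names(rule$antecedent), names(fuzzified))
  if (length(missing_vars))
    stop("no fuzzified degrees supplied for variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  degs <- vapply(names(rule$antecedent), function(v) {
    d <- fuzzified[[v]][[rule$antecedent[[v]]]]
    if (is.null(d) || is.na(d))
      stop("fuzzified degrees for '", v, "' lack term '",
           rule$antecedent[[v]], "'", call. = FALSE)
    d
  }, numeric(1))
  min(degs)
}

# output-term membership matrix on the discretised output universe:
# rows = rules (that rule's consequent), cols = grid points
consequent_grid <- function(system) {
  grid <- seq(system$output$universe[1], system$output$universe[2],
              length.out = system$resolution)
  cons <- t(vapply(system$rules,
                   function(r) membership(system$output$terms[[r$consequent]],
                                          grid),
                   numeric(length(grid))))
  list(grid = grid, cons = cons)
}

#' Aggregate clipped rule consequents
#'
#' Each rule's consequent membership function is truncated (clipped) at the
#' rule's firing strength and the results are combined by pointwise maximum
#' over the discretised output universe.  Rules with zero strength
#' contribute nothing.
#'
#' @param system A [fuzzy_system()].
#' @param strengths Numeric vector of firing strengths, one per rule and in
#'   rule order.
#' @return An object of class `fuzzy_agg` with fields `grid` (evenly spaced
#'   points spanning the output universe) and `degrees` (aggregated
#'   membership at each grid point).
#' @export
aggregate_rules <- function(system, strengths) {
  stopifnot(inherits(system, "fuzzy_system"))
  if (!is.numeric(strengths) || length(strengths) != length(system$rules))
    stop("'strengths' must supply exactly one degree per rule (",
         length(system$rules), ")", call. = FALSE)
  if (any(!is.finite(strengths)) || any(strengths < 0) || any(strengths > 1))
    stop("strengths must be finite degrees in [0, 1]", call. = FALSE)
  cg <- consequent_grid(system)
  clipped <- pmin(cg$cons, strengths)  # strengths recycle down columns
  degrees <- apply(clipped, 2L, max)
  structure(list(grid = cg$grid, degrees = degrees), class = "fuzzy_agg")
}

#' @export
print.fuzzy_agg <- function(x, ...) {
  cat(sprintf("<fuzzy_agg> %d grid points on [%g, %g], max degree %.3f\n",
              length(x$grid), x$grid[1], x$grid[length(x$grid)],
              max(x$degrees)))
  invisible(x)
}

#' Area-centre (centroid) defuzzification
#'
#' Converts an aggregated fuzzy output set into a crisp value via its
#' centre of mass over the discretised universe:
#' `sum(grid * degrees) / sum(degrees)`.
#'
#' @param agg A `fuzzy_agg` from [aggregate_rules()].
#' @return The crisp centroid; strictly inside the output universe whenever
#'   the aggregated set has positive width.
#' @export
defuzzify_centroid <- function(agg) {
  stopifnot(inherits(agg, "fuzzy_agg"))
  s <- sum(agg$degrees)
  if (s <= 0)
    stop("degenerate aggregation: no rule fired (all membership degrees ",
         "are zero); check that the variable terms cover their universes",
         call. = FALSE)
  sum(agg$grid * agg$degrees) / s
}

#' Run Mamdani inference for one set of crisp inputs
#'
#' Composes fuzzification, rule firing, aggregation and centroid
#' defuzzification.  Deterministic for fixed inputs and resolution.
#'
#' @param system A [fuzzy_system()].
#' @param crisp_inputs Named numeric vector or list with one finite value
#'   per input variable (values outside a variable's universe are clamped).
#' @return The crisp output value.
#' @examples
#' sys <- asthma_system()
#' infer(sys, c(pm10 = 20, o3 = 60, so2 = 3, temp_apparent = 22))
#' @export
infer <- function(system, crisp_inputs) {
  stopifnot(inherits(system, "fuzzy_system"))
  crisp_inputs <- unlist(crisp_inputs)
  missing_vars <- setdiff(names(system$inputs), names(crisp_inputs))
  if (length(missing_vars))
    stop("missing crisp input(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  newdata <- as.data.frame(as.list(crisp_inputs[names(system$inputs)]))
  infer_frame(system, newdata)
}

#' Run Mamdani inference for many observations at once
#'
#' Vectorised over rows of a data frame; the aggregation loop runs over the
#' (few) rules rather than the (many) observations, so a year of daily
#' records is inferred in a single pass.
#'
#' @param system A [fuzzy_system()].
#' @param newdata Data frame with one finite numeric column per input
#'   variable.
#' @param chunk Rows per processing block (memory / speed trade-off).
#' @return Numeric vector of crisp outputs, one per row.
#' @export
infer_frame <- function(system, newdata, chunk = 2048L) {
  stopifnot(inherits(system, "fuzzy_system"), is.data.frame(newdata))
  vars <- names(system$inputs)
  missing_vars <- setdiff(vars, names(newdata))
  if (length(missing_vars))
    stop("'newdata' lacks column(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  n <- nrow(newdata)
  if (n == 0L) return(numeric(0))
  for (v in vars) {
    if (!is.numeric(newdata[[v]]) || any(!is.finite(newdata[[v]])))
      stop("column '", v, "' must be finite numeric", call. = FALSE)
  }
  fz <- lapply(system$inputs, function(var) fuzzify_matrix(var, newdata[[var$name]]))
  strengths <- vapply(system$rules, function(r) {
    m <- do.call(pmin, lapply(names(r$antecedent),
                              function(v) fz[[v]][, r$antecedent[[v]]]))
    m
  }, numeric(n))
  strengths <- matrix(strengths, nrow = n)
  cg <- consequent_grid(system)
  res <- length(cg$grid)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    agg <- matrix(0, nrow = length(idx), ncol = res)
    for (r in seq_along(system$rules)) {
      s <- strengths[idx, r]
      if (all(s <= 0)) next
      agg <- pmax(agg, pmin(matrix(s, length(idx), res),
                            matrix(cg$cons[r, ], length(idx), res,
                                   byrow = TRUE)))
    }
    mass <- rowSums(agg)
    if (any(mass <= 0))
      stop("degenerate aggregation for row(s) ",
           paste(idx[mass <= 0], collapse = ", "),
           ": no rule fired", call. = FALSE)
    out[idx] <- as.vector(agg %*% cg$grid) / mass
  }
  out
}
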