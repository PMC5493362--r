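#' Trapezoidal membership function
#'
#' Constructs a piecewise-linear fuzzy set over a real variable.  Membership
#' is 0 at and below `a`, rises linearly to 1 at `b`, stays 1 on `[b, c]`,
#' and falls linearly to 0 at and beyond `d`.  Triangles are obtained with
#' `b == c`; open shoulders (sets that stay at full membership towards one
#' end of the universe) with `a == b` or `c == d`.
#'
#' @param name Term label, e.g. `"good"`.
#' @param breakpoints Numeric vector `c(a, b, c, d)` with
#'   `a <= b <= c <= d`, in the units of the variable.
#' @return An object of class `fuzzy_mf`.
#' @examples
#' good <- mf_trapezoid("good", c(0, 0, 25, 50))
#' membership(good, c(10, 37.5, 60))
#' @export
mf_trapezoid <- function(name, breakpoints) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  bp <- as.numeric(breakpoints)
  if (length(bp) != 4L || anyNA(bp) || any(!is.finite(bp)))
    stop("'breakpoints' must be four finite numbers (a, b, c, d)",
         call. = FALSE)
  if (is.unsorted(bp))
    stop("breakpoints must satisfy a <= b <= c <= d; got (",
         paste(bp, collapse = ", "), ")", call. = FALSE)
  structure(list(name = name, a = bp[1], b = bp[2], c = bp[3], d = bp[4]),
            class = "fuzzy_mf")
}

#' Evaluate a membership function
#'
#' @param mf A [mf_trapezoid()] object.
#' @param x Numeric vector of crisp values (must be finite).
#' @return Membership degrees in `[0, 1]`, one per element of `x`.
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "fuzzy_mf"))
  if (!is.numeric(x) || length(x) == 0L)
    stop("'x' must be numeric", call. = FALSE)
  if (any(!is.finite(x)))
    stop("'x' contains non-finite values", call. = FALSE)
  rise <- if (mf$b > mf$a) (x - mf$a) / (mf$b - mf$a) else as.numeric(x >= mf$a)
  fall <- if (mf$d > mf$c) (mf$d - x) / (mf$d - mf$c) else as.numeric(x <= mf$d)
  pmin(1, pmax(0, pmin(rise, fall)))
}

#' @export
print.fuzzy_mf <- function(x, ...) {
  cat(sprintf("<fuzzy_mf> %s: trapezoid(%g, %g, %g, %g)\n",
              x$name, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Linguistic variable
#'
#' A named quantity (e.g. PM10) described over a closed universe of
#' discourse by a set of named fuzzy terms.  The terms must jointly cover
#' the universe: at every point at least one term has positive membership.
#'
#' @param name Variable name.
#' @param universe Numeric `c(lo, hi)` with `lo < hi`, in variable units.
#' @param terms List of [mf_trapezoid()] objects with unique names.
#' @return An object of class `fuzzy_variable`.
#' @examples
#' pm10 <- fuzzy_variable("pm10", c(0, 120), list(
#'   mf_trapezoid("good", c(0, 0, 25, 50)),
#'   mf_trapezoid("bad",  c(25, 50, 120, 120))))
#' fuzzify(pm10, 37.5)
#' @export
fuzzy_variable <- function(name, universe, terms) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  universe <- as.numeric(universe)
  if (length(universe) != 2L || any(!is.finite(universe)) ||
      universe[1] >= universe[2])
    stop("'universe' must be c(lo, hi) with lo < hi", call. = FALSE)
  if (!is.list(terms) || length(terms) == 0L ||
      !all(vapply(terms, inherits, logical(1), "fuzzy_mf")))
    stop("'terms' must be a non-empty list of fuzzy_mf objects",
         call. = FALSE)
  term_names <- vapply(terms, `[[`, character(1), "name")
  if (anyDuplicated(term_names))
    stop("term names within variable '", name, "' must be unique",
         call. = FALSE)
  names(terms) <- term_names
  eps <- 1e-8 * diff(universe)
  for (tm in terms) {
    if (tm$a < universe[1] - eps || tm$d > universe[2] + eps)
      stop("term '", tm$name, "' of variable '", name,
           "' has breakpoints outside the universe [",
           universe[1], ", ", universe[2], "]", call. = FALSE)
  }
  obj <- structure(list(name = name, universe = universe, terms = terms),
                   class = "fuzzy_variable")
  # coverage: every point of the universe belongs to at least one term
  grid <- seq(universe[1], universe[2], length.out = 257L)
  cover <- Reduce(pmax, lapply(terms, membership, x = grid))
  if (any(cover <= 0))
    stop("terms of variable '", name,
         "' do not cover the universe (zero membership at, e.g., x = ",
         signif(grid[which(cover <= 0)[1]], 4), ")", call. = FALSE)
  obj
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  cat(sprintf("<fuzzy_variable> %s on [%g, %g] with %d terms: %s\n",
              x$name, x$universe[1], x$universe[2], length(x$terms),
              paste(names(x$terms), collapse = ", ")))
  invisible(x)
}

#' Fuzzify a crisp value
#'
#' Maps a crisp measurement to its degree of membership in every term of a
#' linguistic variable.  Values outside the declared universe are clamped
#' to `[lo, hi]` first, so out-of-range readings (e.g. a pollution episode
#' above the historical maximum) still fuzzify cleanly.
#'
#' @param var A [fuzzy_variable()].
#' @param x A single finite crisp value.
#' @return Named numeric vector of degrees in `[0, 1]`, one per term.
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "fuzzy_variable"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'x' must be a single finite number", call. = FALSE)
  drop(fuzzify_matrix(var, x))
}

# vectorised fuzzification: rows = observations, cols = terms
fuzzify_matrix <- function(var, x) {
  x <- pmin(var$universe[2], pmax(var$universe[1], x))
  out <- vapply(var$terms, membership, numeric(length(x)), x = x)
  if (length(x) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, names(var$terms)))
  out
}
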