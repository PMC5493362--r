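#' Convert a fuzzy system to a plain configuration list
#'
#' The list mirrors the on-disk configuration format: variables with
#' universes and trapezoid breakpoints, rules as term-name tuples, and the
#' resolution.  `system_from_config()` inverts it; the round trip is
#' lossless.
#'
#' @param system A [fuzzy_system()].
#' @return A nested list suitable for [write_model_config()].
#' @export
system_to_config <- function(system) {
  stopifnot(inherits(system, "fuzzy_system"))
  var_cfg <- function(v) list(
    name = v$name,
    universe = as.numeric(v$universe),
    terms = lapply(unname(v$terms), function(tm)
      list(name = tm$name, breakpoints = c(tm$a, tm$b, tm$c, tm$d)))
  )
  list(
    inputs = lapply(unname(system$inputs), var_cfg),
    output = var_cfg(system$output),
    rules = lapply(system$rules, function(r)
      list(when = as.list(r$antecedent), then = r$consequent)),
    resolution = system$resolution
  )
}

#' @rdname system_to_config
#' @param config A configuration list as produced by [system_to_config()]
#'   or read from YAML/JSON.
#' @export
system_from_config <- function(config) {
  req <- c("inputs", "output", "rules", "resolution")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("configuration lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  var_from <- function(vc) {
    fuzzy_variable(vc$name, unlist(vc$universe),
                   lapply(vc$terms, function(tc)
                     mf_trapezoid(tc$name, unlist(tc$breakpoints))))
  }
  rules <- lapply(config$rules, function(rc) {
    ant <- unlist(rc$when)
    fuzzy_rule(ant, rc$then)
  })
  fuzzy_system(lapply(config$inputs, var_from), var_from(config$output),
               rules, resolution = config$resolution)
}

#' Read / write a fuzzy model configuration file
#'
#' The configuration format is YAML (`.yml`/`.yaml`) or JSON (`.json`),
#' chosen by the file extension.  Loading a saved configuration and
#' rebuilding the system reproduces the original predictions exactly.
#'
#' @param system A [fuzzy_system()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a [fuzzy_system()].
#' @export
write_model_config <- function(system, path) {
  cfg <- system_to_config(system)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported configuration extension '.", ext,
         "' (use .yaml, .yml or .json)", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unsupported configuration extension '.", ext,
         "' (use .yaml, .yml or .json)", call. = FALSE)
  }
  # a file may carry a severity map instead of explicit rules
  if (is.null(cfg$rules) && !is.null(cfg$severity_map))
    cfg$rules <- lapply(asthma_rules(unlist(cfg$severity_map),
                                     input_names = vapply(cfg$inputs, `[[`,
                                                          character(1), "name")),
                        function(r) list(when = as.list(r$antecedent),
                                         then = r$consequent))
  system_from_config(cfg)
}
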