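#' Write a parameter set to a YAML configuration file
#'
#' The configuration is a single human-readable YAML document carrying a
#' `schema_version` key; the embedded life table is serialised as parallel
#' `age`/`sex`/`qx` columns.  `load_config()` inverts this exactly.
#'
#' @param params a valid `cea_params` object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  assert_valid_parameters(params)
  x <- unclass(params)
  x$life_table <- as.list(x$life_table[c("age", "sex", "qx")])
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a parameter set from a YAML configuration file
#'
#' Validates every invariant on load and fails with the offending keys.
#'
#' @param path configuration file written by [write_config()] (or by hand,
#'   following the same schema).
#' @return a `cea_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  required <- c("schema_version", "population", "arms", "utility", "costs",
                "settings", "life_table")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("config missing top-level field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x$schema_version <- as.integer(x$schema_version)
  x$settings$rng_seed <- as.integer(x$settings$rng_seed)
  x$life_table <- data.frame(age = as.numeric(x$life_table$age),
                             sex = as.character(x$life_table$sex),
                             qx  = as.numeric(x$life_table$qx))
  class(x) <- "cea_params"
  assert_valid_parameters(x)
  x
}

#' Read / write a life table
#'
#' Delimited text with header `age,sex,qx`.
#'
#' @param path CSV file.
#' @return data frame with columns `age`, `sex`, `qx`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "sex", "qx") %in% names(lt)))
    stop("life table must have columns age, sex, qx", call. = FALSE)
  lt
}

#' @rdname read_life_table
#' @param life_table data frame with columns `age`, `sex`, `qx`.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table[c("age", "sex", "qx")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Get or set a parameter by path
#'
#' Parameters are addressed by a `/`-separated path through the nested
#' parameter list, e.g. `"utility/slope_per_mmd"`,
#' `"arms/intervention/response_prob"` or
#' `"costs/resources/hospitalisation/unit_cost"`.  Used by the tornado
#' analysis and scenario overlays.
#'
#' @param params a `cea_params` object.
#' @param path character path.
#' @return `get_param`: the value; `set_param`: the modified parameter set.
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  x <- params
  for (k in keys) {
    if (is.null(x[[k]]))
      stop("unknown parameter path: ", path, " (no component '", k, "')",
           call. = FALSE)
    x <- x[[k]]
  }
  x
}

#' @rdname get_param
#' @param value replacement value.
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  get_param(params, path)  # errors on unknown path
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys,
                 accumulate = FALSE, init = quote(params))
  eval(call("<-", expr, value))
  params
}
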