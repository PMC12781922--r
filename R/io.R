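#' Read and write the long-format visits CSV
#'
#' The interchange format is one row per assessment with header
#' `subject_id,time,outcome` (extra covariate columns are preserved).  Every
#' subject has a `time = 0` baseline row; a subject with no follow-up is
#' represented by having only that row.  Times are written as full-precision
#' decimal text so a write/read cycle round-trips exactly.  Lines starting
#' with `#` hold provenance (seed, config hash) and are skipped on read.
#'
#' @param path file path.
#' @return `read_visits()`: a data frame sorted by subject and time.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (!is.numeric(df$time) || anyNA(df$time))
    stop(sprintf("%s: column 'time' must be numeric with no missing values",
                 path))
  if (!is.numeric(df$outcome))
    stop(sprintf("%s: column 'outcome' must be numeric", path))
  dup <- duplicated(df[, c("subject_id", "time")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("%s: duplicate (subject_id, time) at data row %d: (%s, %g)",
                 path, i, df$subject_id[i], df$time[i]))
  }
  df <- df[order(df$subject_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_visits
#' @param x an `"iiw_cohort"` or a long visits data frame.
#' @param provenance optional named list written as `# name: value` header
#'   lines (e.g. seed and config hash).
#' @export
write_visits <- function(x, path, provenance = NULL) {
  df <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, format(provenance[[nm]], digits = 17)),
               con)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write counting-process CSV
#'
#' Columns `subject_id,start,stop,event` plus one or more covariate columns
#' (`z`, or `z1, z2, ...`).
#'
#' @param path file path.
#' @return `read_counting()`: a validated data frame.
#' @export
read_counting <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "start", "stop", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (!length(setdiff(names(df), need)))
    stop(sprintf("%s: no covariate columns", path))
  bad <- which(!(df$start < df$stop))
  if (length(bad))
    stop(sprintf("%s: row %d has start >= stop", path, bad[1L]))
  if (!all(df$event %in% c(0, 1)))
    stop(sprintf("%s: 'event' must be 0/1", path))
  df
}

#' @rdname read_counting
#' @param x a counting-process data frame.
#' @param provenance optional named list of `# name: value` header lines.
#' @export
write_counting <- function(x, path, provenance = NULL) {
  write_table_prov(x, path, provenance)
}

# full-precision CSV with `# key: value` provenance header lines
write_table_prov <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, format(provenance[[nm]], digits = 17)),
               con)
  write.csv(format(as.data.frame(x), digits = 17, trim = TRUE,
                   scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_schema <- list(
  seed = "integer", out_dir = "character", verbose = "logical",
  simulate = list(n_subjects = "count", mechanism = "mechanism", lambda0 = "nonneg",
                  gamma0 = "number", tau = "positive", sigma_u = "positive",
                  sigma_v = "positive", rho_uv = "correlation",
                  sigma_eps = "positive", range = "positive",
                  nugget = "unit"),
  fit = list(scheme = "scheme", tau = "positive"),
  bias_theory = list(dist = "dist", p = "unit_open", gamma = "number",
                     lambda0 = "positive", tau = "positive",
                     axis = "axis", grid = "numvec", order = "order"),
  experiment = list(parameter = "parameter", values = "numvec",
                    mechanisms = "numvec", n_reps = "count", n_subjects = "count",
                    lambda0 = "nonneg", gamma0 = "number", tau = "positive"))

check_cfg_value <- function(value, rule, key) {
  ok <- switch(rule,
    integer = is.numeric(value) && value == round(value),
    count = is.numeric(value) && value >= 1 && value == round(value),
    number = is.numeric(value) && is.finite(value),
    nonneg = is.numeric(value) && value >= 0,
    positive = is.numeric(value) && value > 0,
    correlation = is.numeric(value) && abs(value) < 1,
    unit = is.numeric(value) && value >= 0 && value < 1,
    unit_open = is.numeric(value) && value > 0 && value < 1,
    mechanism = value %in% c(1, 2),
    scheme = value %in% c("EV", "FU"),
    dist = value %in% c("bernoulli", "normal01", "gamma11"),
    axis = value %in% c("lambda0", "tau", "lambda0_tau_fixed_product",
                        "gamma_fixed_visits"),
    order = value %in% c("asymptotic", "first"),
    parameter = value %in% c("lambda0", "tau", "gamma0", "n_large",
                             "n_small"),
    numvec = is.numeric(value) && length(value) >= 1,
    character = is.character(value),
    logical = is.logical(value))
  if (!isTRUE(ok))
    stop(sprintf("config field '%s': invalid value (%s expected)", key, rule))
  invisible(TRUE)
}

#' Read a structured run configuration
#'
#' YAML with optional top-level keys `seed`, `out_dir`, `verbose` and
#' parameter blocks `simulate`, `fit`, `bias_theory`, `experiment`.  Every
#' numeric field is range-checked at parse time; unknown keys anywhere are
#' rejected with the file and offending key named.
#'
#' @param path YAML file path.
#' @return A validated list of class `"run_config"` with attribute
#'   `"md5"` (hash of the file, for provenance).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop(sprintf("%s: config must be a YAML mapping", path))
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(unknown, collapse = ", ")))
  for (blk in names(cfg)) {
    rule <- config_schema[[blk]]
    if (is.list(rule)) {
      if (!is.list(cfg[[blk]]))
        stop(sprintf("%s: block '%s' must be a mapping", path, blk))
      unknown <- setdiff(names(cfg[[blk]]), names(rule))
      if (length(unknown))
        stop(sprintf("%s: unknown key(s) in block '%s': %s", path, blk,
                     paste(unknown, collapse = ", ")))
      for (key in names(cfg[[blk]]))
        check_cfg_value(cfg[[blk]][[key]], rule[[key]],
                        paste(blk, key, sep = "."))
    } else {
      check_cfg_value(cfg[[blk]], rule, blk)
    }
  }
  structure(cfg, class = "run_config", md5 = unname(tools::md5sum(path)))
}
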