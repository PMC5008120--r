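# Summary statistics, config parsing, TSV writers, and run manifests.

#' Ratio of the rarest to commonest mating-type allele
#'
#' A distortion statistic for the mating-type distribution: the minimum
#' allele count divided by the maximum. A value of 1 means a perfectly even
#' distribution. By default alleles with zero count (extinct) are excluded
#' from the minimum, so the statistic tracks distortion among extant types
#' rather than collapsing to 0 at the first extinction; set
#' `include_extinct = TRUE` for the alternative convention where any
#' extinction pins the ratio at 0.
#'
#' @param type_counts Integer vector of per-allele counts, at least one
#'   positive.
#' @param include_extinct Count zero-count alleles in the minimum?
#' @return A ratio in `[0, 1]`.
#' @examples
#' rare_common_ratio(c(10, 40))       # 0.25
#' rare_common_ratio(c(0, 30, 10))    # 1/3: extinct allele excluded
#' rare_common_ratio(c(0, 30, 10), include_extinct = TRUE)  # 0
#' @export
rare_common_ratio <- function(type_counts, include_extinct = FALSE) {
  if (length(type_counts) == 0L || anyNA(type_counts) || any(type_counts < 0))
    abort_validation("parameter 'type_counts' must be non-negative counts")
  if (all(type_counts == 0))
    abort_validation("parameter 'type_counts' is all zero (empty population)")
  lo <- if (include_extinct) min(type_counts) else min(type_counts[type_counts > 0])
  lo / max(type_counts)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (>= 1).
#' @param level Coverage level, default 0.95.
#' @return Numeric vector `c(lower, upper)`; always contains the point
#'   estimate `successes / trials`.
#' @examples
#' wilson_interval(5, 10)
#' @export
wilson_interval <- function(successes, trials, level = 0.95) {
  trials <- check_count(trials, "trials", 1L)
  successes <- check_count(successes, "successes", 0L)
  if (successes > trials)
    abort_validation("parameter 'successes' (%d) exceeds 'trials' (%d)",
                     successes, trials)
  level <- check_prob(level, "level")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z / denom * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Write a tidy tab-separated table
#'
#' Writes a data frame as TSV with a header row, no quoting, `.` decimal
#' separator, and Unix newlines. Numeric columns keep full precision so
#' values round-trip losslessly.
#'
#' @param records A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_table(data.frame(x = 1:3, y = c(0.1, 0.25, 1/3)), f)
#' readLines(f)
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format(out[[j]], digits = 15,
                                                trim = TRUE, scientific = FALSE)
  }
  tryCatch(
    write.table(out, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, eol = "\n"),
    error = function(e) stop(sprintf("cannot write table to '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' The file holds one `key = value` pair per line (keys exactly the
#' [lifecycle_params()] field names); blank lines and lines starting with
#' `#` are ignored. Unknown keys are an error; missing keys fall back to
#' the documented defaults.
#'
#' @param path Path to the config file.
#' @param overrides Named list of values taking precedence over the file
#'   (used by the CLI's `--set` flags).
#' @return A validated [lifecycle_params()] object.
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' writeLines(c("N = 50", "g = 5", "seed = 7"), f)
#' read_config(f)$N
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  values <- list()
  for (line in lines) {
    if (!grepl("=", line, fixed = TRUE))
      abort_validation("malformed config line (expected 'key = value'): '%s'", line)
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!key %in% names(.param_defaults))
      abort_validation("unknown config key '%s' (known keys: %s)",
                       key, paste(names(.param_defaults), collapse = ", "))
    values[[key]] <- coerce_param(val, key)
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(.param_defaults))
    if (length(bad))
      abort_validation("unknown parameter override '%s'", bad[[1L]])
    values <- modifyList(values, overrides)
  }
  do.call(lifecycle_params, values)
}

#' Run manifest for an experiment harness
#'
#' Captures everything needed to reproduce a result table: the full
#' parameter set, the base seed, the replicate count, the harness name, a
#' timestamp, and the package version. Identical manifests run against an
#' identical implementation yield identical tables.
#'
#' @param params A [lifecycle_params()] object.
#' @param harness Harness name (e.g. `"fixation"`).
#' @param replicates Replicate count used.
#' @param extra Named list of harness-specific settings to record.
#' @return A list of class `run_manifest`.
#' @seealso [write_manifest()], [read_manifest()]
#' @examples
#' run_manifest(lifecycle_params(), "fixation", 100)$harness
#' @export
run_manifest <- function(params, harness, replicates, extra = list()) {
  stopifnot(inherits(params, "lifecycle_params"))
  structure(list(
    harness = harness,
    parameters = unclass(params),
    base_seed = params$seed,
    replicates = replicates,
    settings = extra,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(packageVersion("switchsim"))
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest` object.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$settings <- as.list(x$settings)
  structure(x, class = "run_manifest")
}
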