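# declarative config schemas, one per pipeline. Each field:
# list(required = , default = , check = function(v) TRUE or message)
.cfg_schemas <- function() {
  num_in <- function(lo, hi) function(v) {
    if (!is.numeric(v) || length(v) != 1 || v < lo || v > hi)
      sprintf("must be a number in [%g, %g]", lo, hi) else TRUE
  }
  list(
    ps = list(
      pipeline = list(required = TRUE),
      images = list(required = TRUE, check = function(v) {
        if (!is.list(v) || length(v) < 2)
          return("needs at least 2 image entries")
        for (e in v) {
          if (!all(c("path", "ps", "qs") %in% names(e)))
            return("every image entry needs path, ps, qs")
          if (!is.numeric(e$ps) || !is.numeric(e$qs))
            return("ps and qs must be numeric")
        }
        TRUE
      }),
      method = list(default = "lsq", check = function(v)
        if (!v %in% c("exact", "lsq", "two_source"))
          "must be one of exact, lsq, two_source" else TRUE),
      shadow_low = list(default = 0.02, check = num_in(0, 1)),
      shadow_high = list(default = 0.98, check = num_in(0, 1)),
      pixel_pitch = list(default = NULL, check = function(v)
        if (!is.null(v) && (!is.numeric(v) || v <= 0))
          "must be a positive number" else TRUE)
    ),
    weeds = list(
      pipeline = list(required = TRUE),
      image = list(required = TRUE),
      window_px = list(default = 32, check = num_in(2, 1024)),
      n_levels = list(default = 64, check = num_in(2, 65536)),
      threshold_bits = list(default = NULL, check = function(v)
        if (!is.null(v) && (!is.numeric(v) || v < 0))
          "must be NULL (auto) or a non-negative number" else TRUE),
      open_px = list(default = 5, check = num_in(0, 99)),
      close_px = list(default = 9, check = num_in(0, 99)),
      min_area_px = list(default = 200, check = num_in(0, 1e7))
    ),
    potatoes = list(
      pipeline = list(required = TRUE),
      frames = list(required = TRUE),
      band_edges = list(default = c(45, 65, 80), check = function(v)
        if (!is.numeric(v) || any(diff(v) <= 0))
          "must be strictly increasing numerics" else TRUE),
      min_height_mm = list(default = 8, check = num_in(0.1, 500)),
      min_area_px = list(default = 150, check = num_in(1, 1e6)),
      max_residual_mm = list(default = 3, check = num_in(0.1, 100)),
      belt_percentile = list(default = 60, check = num_in(50, 100))
    ),
    map = list(
      pipeline = list(required = TRUE),
      records = list(required = TRUE),
      gps = list(required = TRUE),
      cell_size_m = list(default = 5, check = num_in(0.1, 1000)),
      window_s = list(default = 5, check = num_in(0, 3600))
    )
  )
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML config, checks it against the schema of its `pipeline`
#' (unknown keys rejected; missing required keys, type and range
#' violations all reported together in one error), fills documented
#' defaults and records which keys were defaulted.
#'
#' @param path YAML config file.
#' @param pipeline expected pipeline name; default: the config's own
#'   `pipeline` key.
#' @return a `run_config` list with an extra `defaulted` character
#'   vector naming keys that took default values.
#' @export
validate_config <- function(path, pipeline = NULL) {
  .assert(file.exists(path), "config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  .assert(is.list(cfg), "%s: config must be a key/value mapping", path)
  schemas <- .cfg_schemas()
  pl <- cfg$pipeline
  if (is.null(pl)) pl <- pipeline
  violations <- character(0)
  if (is.null(pl) || !pl %in% names(schemas)) {
    stop(sprintf("%s: unknown or missing pipeline '%s' (known: %s)", path,
                 if (is.null(pl)) "" else pl,
                 paste(names(schemas), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(pipeline) && pl != pipeline)
    violations <- c(violations,
                    sprintf("pipeline is '%s', expected '%s'", pl, pipeline))
  schema <- schemas[[pl]]
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0)
    violations <- c(violations,
                    sprintf("unknown key '%s'", unknown))
  defaulted <- character(0)
  for (key in names(schema)) {
    fs <- schema[[key]]
    if (is.null(cfg[[key]])) {
      if (isTRUE(fs$required)) {
        violations <- c(violations, sprintf("missing required key '%s'", key))
      } else if (!is.null(fs$default)) {
        cfg[[key]] <- fs$default
        defaulted <- c(defaulted, key)
      }
      next
    }
    if (!is.null(fs$check)) {
      res <- fs$check(cfg[[key]])
      if (!isTRUE(res))
        violations <- c(violations, sprintf("key '%s' %s", key, res))
    }
  }
  # ps-specific cross-field checks
  if (pl == "ps" && length(violations) == 0 && !is.null(cfg$images)) {
    method <- if (is.null(cfg$method)) "lsq" else cfg$method
    n <- length(cfg$images)
    if (method %in% c("exact", "lsq") && n < 3)
      violations <- c(violations, sprintf(
        "a full photometric-stereo solve needs at least 3 lights (got %d)", n))
    if (method %in% c("exact", "lsq") && n >= 3) {
      ls <- light_set(vapply(cfg$images, `[[`, 0, "ps"),
                      vapply(cfg$images, `[[`, 0, "qs"))
      ok <- tryCatch({ .check_light_rank(ls); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) violations <- c(violations, ok)
    }
  }
  if (length(violations) > 0)
    stop(sprintf("%s: invalid configuration:\n  - %s", path,
                 paste(violations, collapse = "\n  - ")), call. = FALSE)
  cfg$defaulted <- defaulted
  class(cfg) <- "run_config"
  cfg
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records inputs (with MD5 hashes), the resolved configuration, the
#' seed, and package/R versions — enough to reproduce the run
#' bit-for-bit (stochastic stages are fixed by the seed).
#'
#' @param out_dir run output directory.
#' @param config resolved `run_config` (or any list).
#' @param inputs character vector of input file paths.
#' @param seed integer seed used for the run (or NULL).
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config = NULL, inputs = character(0),
                           seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- inputs[file.exists(inputs)]
  man <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "fieldvision",
    package_version = as.character(packageVersion("fieldvision")),
    r_version = R.version.string,
    seed = seed,
    inputs = if (length(inputs) > 0)
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    else NULL,
    config = if (inherits(config, "run_config")) unclass(config) else config)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(p)
}
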