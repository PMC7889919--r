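#' @title Run configuration and output writers
#' @description YAML/JSON run configurations (frequencies, exposure levels,
#'   ages, factor toggles, age-table anchors, Monte Carlo settings) with
#'   validation and defaulting, plus deterministic CSV/JSON writers and a run
#'   manifest recording the resolved configuration hash and seed.
#' @name io_config
NULL

.default_config <- function() {
  list(
    frequencies_GHz = c(26, 60),
    ipd = 10,
    ages = c(5, 7, 12, 30, 35, 45, 65, 70),
    factors = c("thickness", "permittivity", "blood_flow"),
    mc_trials = 0,
    mc_anchor_ages = c(7, 12, 30, 45, 65),
    seed = 1,
    age_tables = NULL,            # NULL -> default_age_tables()
    literal_table_split = FALSE,
    constants = list()
  )
}

#' Load and validate a run configuration
#'
#' Reads YAML (or JSON) into a fully defaulted, validated configuration and
#' echoes every resolved value. Anchor tables may be given inline under
#' `age_tables: {parameter: [{age, mean, sd}, ...]}`.
#'
#' @param path file path to a YAML or JSON configuration.
#' @param quiet logical; suppress the resolved-value echo.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- .default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(raw)] <- raw

  stopifnot(is.numeric(cfg$frequencies_GHz), all(cfg$frequencies_GHz > 0),
            is.numeric(cfg$ages), all(cfg$ages >= 0),
            is.numeric(cfg$mc_trials), cfg$mc_trials >= 0,
            is.numeric(cfg$seed))
  if (!is.numeric(cfg$ipd) && !all(cfg$ipd %in%
        c("icnirp_general", "icnirp_occupational"))) {
    stop("config field ipd: must be numeric or icnirp_general/icnirp_occupational")
  }
  if (length(cfg$factors)) {
    cfg$factors <- match.arg(cfg$factors,
                             c("thickness", "permittivity", "blood_flow"),
                             several.ok = TRUE)
  }
  if (!is.null(cfg$age_tables)) {
    anchors <- lapply(cfg$age_tables, function(a) {
      if (is.data.frame(a)) a
      else if (!is.null(names(a))) as.data.frame(a)            # column lists
      else do.call(rbind, lapply(a, as.data.frame))            # row records
    })
    cfg$tables <- make_age_tables(anchors)
  } else {
    cfg$tables <- default_age_tables()
  }
  cfg$const <- dosimetry_constants(cfg$constants)
  if (!quiet) {
    message("resolved run configuration:")
    for (f in c("frequencies_GHz", "ipd", "ages", "factors", "mc_trials",
                "mc_anchor_ages", "seed", "literal_table_split")) {
      message("  ", f, " = ", paste(format(cfg[[f]]), collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

#' Serialise a run configuration back to YAML
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
dump_run_config <- function(cfg, path) {
  keep <- intersect(names(.default_config()), names(cfg))
  out <- cfg[keep]
  out$constants <- if (length(out$constants)) out$constants else NULL
  yaml::write_yaml(out[!vapply(out, is.null, logical(1))], path)
  invisible(path)
}

#' Write run outputs with a manifest
#'
#' Writes each element of `results` (data.frames as CSV, other lists as
#' JSON) plus `manifest.json` recording the configuration hash, seed and
#' package version. Given the same configuration and seed the files are
#' byte-identical across runs.
#'
#' @param results named list of data.frames and/or lists.
#' @param dir output directory.
#' @param config optional `run_config` recorded in the manifest.
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(results, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(is.list(results))
  if (length(results)) stopifnot(!is.null(names(results)))
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, path, row.names = FALSE)
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    files <- c(files, path)
  }
  cfg_hash <- if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    keep <- intersect(names(.default_config()), names(config))
    jsonlite::write_json(config[keep], tmp, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    unname(tools::md5sum(tmp))
  } else NA_character_
  manifest <- list(
    files = basename(files),
    config_md5 = cfg_hash,
    seed = if (!is.null(config)) config$seed else NA,
    package_version = as.character(utils::packageVersion("agederm")))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, mpath))
}
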