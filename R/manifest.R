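# Run manifests: enough metadata to re-run a pipeline step bit-identically
# (given fixed library versions).

#' Write a run manifest
#'
#' @param path output JSON path.
#' @param command the CLI subcommand or calling function.
#' @param config named list of configuration values (seed included).
#' @param artifacts named list/vector of output paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(),
                               artifacts = list()) {
  manifest <- list(
    command = command,
    config = config,
    artifacts = artifacts,
    package = as.character(utils::packageVersion("nasols")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest JSON path.
#' @return named list.
#' @export
read_run_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Parse a plain-text key=value config file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are parsed
#' as numbers when possible, otherwise kept as strings; comma-separated
#' values become vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}
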