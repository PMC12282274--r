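#' Pipeline configuration
#'
#' All shipped defaults are the published analysis parameters: a 110-residue
#' head window; the 50% identity / 90% coverage group rule and the 65%
#' subgroup rule; genome-mode read filters 80/50; contig-mode read filters
#' 86/95/55; significance level 0.01. Every value can be overridden.
#'
#' @param head_length Head window length.
#' @param group_min_identity,group_min_coverage,subgroup_min_identity
#'   Grouping thresholds (percent).
#' @param genome_min_identity,genome_min_aligned Genome-mode read filters.
#' @param contig_min_identity,contig_min_aligned,contig_min_covered
#'   Contig-mode read filters.
#' @param alpha Significance level for strain comparisons.
#' @param seed Integer seed used by simulation commands.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(head_length = 110,
                            group_min_identity = 50,
                            group_min_coverage = 90,
                            subgroup_min_identity = 65,
                            genome_min_identity = 80,
                            genome_min_aligned = 50,
                            contig_min_identity = 86,
                            contig_min_aligned = 95,
                            contig_min_covered = 55,
                            alpha = 0.01,
                            seed = 1) {
  structure(
    list(
      head_length = head_length,
      group_min_identity = group_min_identity,
      group_min_coverage = group_min_coverage,
      subgroup_min_identity = subgroup_min_identity,
      genome_min_identity = genome_min_identity,
      genome_min_aligned = genome_min_aligned,
      contig_min_identity = contig_min_identity,
      contig_min_aligned = contig_min_aligned,
      contig_min_covered = contig_min_covered,
      alpha = alpha,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat("  ", k, " = ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}

#' Write a configuration to a flat key-value file
#'
#' One `key = value` line per setting (a flat TOML-style dialect), so the
#' parameter provenance of a run is auditable. Round-trips losslessly
#' through [read_config()].
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- purrr::map_chr(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]], digits = 15))
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to a file written by [write_config()] (or hand-edited
#'   in the same format; `#` comments and blank lines are ignored).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  lines <- readLines(path)
  lines <- stringr::str_trim(gsub("#.*$", "", lines))
  lines <- lines[nchar(lines) > 0]
  defaults <- pipeline_config()
  vals <- list()
  for (ln in lines) {
    m <- stringr::str_match(ln, "^([A-Za-z0-9_]+)\\s*=\\s*(.+)$")
    if (is.na(m[1, 1])) abort(paste0("Malformed config line: ", ln))
    key <- m[1, 2]
    if (!key %in% names(defaults)) abort(paste0("Unknown config key: ", key))
    vals[[key]] <- as.numeric(m[1, 3])
  }
  do.call(pipeline_config, utils::modifyList(unclass(defaults), vals))
}

#' Write a run manifest
#'
#' Records the package version, the full configuration, MD5 checksums of the
#' input and output files, the seed, warnings surfaced during the run, and
#' timestamps — enough to reproduce the run byte-identically.
#'
#' @param path Manifest output path (JSON).
#' @param command Command name.
#' @param config The [pipeline_config()] used.
#' @param inputs,outputs Character vectors of file paths to checksum.
#' @param warnings Character vector of warnings surfaced during the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character(),
                           outputs = character(), warnings = character()) {
  checksum <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  manifest <- list(
    tool = "rbptools",
    version = as.character(utils::packageVersion("rbptools")),
    command = command,
    config = unclass(config),
    seed = config$seed,
    input_md5 = checksum(inputs),
    output_md5 = checksum(outputs),
    warnings = as.list(warnings),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
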