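# Output plumbing shared by the analysis drivers: table writers and the run
# manifest that makes every output directory reproducible.

#' Write a data frame as CSV
#'
#' @param df Data frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a list as JSON
#'
#' @param x A list (unboxed scalars, full numeric precision).
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced the contents of an output directory: the input
#' file paths and their checksums, the seed, the package version, the
#' command label and a timestamp. Reruns with identical manifest inputs
#' reproduce identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param inputs Character vector of input file paths to checksum.
#' @param seed The seed used, or `NA` for deterministic stages.
#' @param command Free-text label of the producing command.
#' @return The manifest path, invisibly.
#' @export
run_manifest <- function(out_dir, inputs = character(0), seed = NA,
                         command = "") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    seed = seed,
    package_version = as.character(utils::packageVersion("bariaCEA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = if (length(inputs) > 0) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else list()
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
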