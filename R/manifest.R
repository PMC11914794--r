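#' Write a run manifest beside an output file
#'
#' Records tool version, subcommand, resolved parameters, input file digests
#' and a timestamp as JSON next to an output, so every artifact carries its
#' provenance.
#'
#' @param output Path of the primary output file.
#' @param subcommand Name of the step that produced it.
#' @param params Named list of resolved parameters.
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(output, subcommand, params = list(),
                           inputs = character()) {
  digests <- lapply(inputs, function(p) {
    if (file.exists(p)) {
      list(path = p, md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    } else {
      list(path = p, md5 = NA, bytes = NA)
    }
  })
  manifest <- list(
    tool = "neoscreen",
    version = as.character(utils::packageVersion("neoscreen")),
    subcommand = subcommand,
    parameters = params,
    inputs = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- paste0(output, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
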