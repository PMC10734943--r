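#' Toolkit configuration
#'
#' Bundles the tunable parameters of the pipeline: the consensus pattern,
#' the RING expression, the ID-parsing scheme, the mismatch tolerance, the
#' tandem-cluster threshold, the percentage-display convention, and a
#' ploidy table. Defaults are the published pattern strings and the
#' conventions used throughout the package.
#'
#' @param consensus_pattern Degenerate consensus pattern string.
#' @param ring_pattern RING regular expression string.
#' @param id_scheme `"dot_suffix"` or `"custom_regex"`.
#' @param id_regex Regex for the custom scheme.
#' @param max_mismatches Motif-scan mismatch tolerance.
#' @param max_intervening Tandem-cluster intervening-gene threshold.
#' @param truncate_percentages Truncate (not round) displayed percentages.
#' @param ploidy Named list/vector mapping `species_tag` to a ploidy class.
#' @return A list of class `sina_config`.
#' @export
sina_config <- function(consensus_pattern = sina_consensus_pattern(),
                        ring_pattern = sina_ring_pattern(),
                        id_scheme = "dot_suffix",
                        id_regex = NULL,
                        max_mismatches = 0L,
                        max_intervening = 1L,
                        truncate_percentages = TRUE,
                        ploidy = list()) {
  structure(
    list(
      consensus_pattern = consensus_pattern,
      ring_pattern = ring_pattern,
      id_scheme = id_scheme,
      id_regex = id_regex,
      max_mismatches = max_mismatches,
      max_intervening = max_intervening,
      truncate_percentages = truncate_percentages,
      ploidy = ploidy
    ),
    class = "sina_config"
  )
}

#' Read/write a configuration as JSON
#'
#' @param path JSON file path.
#' @return For the reader, a `sina_config`; the writer returns `path`
#'   invisibly.
#' @export
read_sina_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- sina_config()
  for (k in names(raw)) defaults[[k]] <- raw[[k]]
  defaults
}

#' @rdname read_sina_config
#' @param config A `sina_config`.
#' @export
write_sina_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}
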