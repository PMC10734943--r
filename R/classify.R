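#' The four SINA classes
#'
#' Cross of \{ancestral vs modified SINA motif\} x \{RING present vs
#' absent\}, in the fixed order used by all summaries.
#'
#' @return Character vector of the four class labels.
#' @export
sina_classes <- function() {
  c("ancestral_with_ring", "ancestral_without_ring",
    "modified_with_ring", "modified_without_ring")
}

sina_class_of <- function(has_ancestral, has_ring) {
  dplyr::case_when(
    has_ancestral & has_ring ~ "ancestral_with_ring",
    has_ancestral & !has_ring ~ "ancestral_without_ring",
    !has_ancestral & has_ring ~ "modified_with_ring",
    TRUE ~ "modified_without_ring"
  )
}

#' Classify a single candidate SINA sequence
#'
#' Two-factor classification: first scan for the ancestral SINA motif,
#' then for a canonical RING domain; the pair of presence calls maps to one
#' of the four classes. The input is assumed to be a SINA-family candidate;
#' family membership screening (homology + external domain scanners) is a
#' separate, upstream concern.
#'
#' @param sequence A non-empty amino-acid string.
#' @param motif A `degenerate_motif`; default the ancestral SINA motif.
#' @param max_mismatches Mismatch tolerance for the motif scan (default 0).
#' @param ring_pattern RING regular expression.
#' @return A one-row tibble: `sina_class`, `n_ancestral_hits`,
#'   `ancestral_start`, `ancestral_end`, `ring_start`, `ring_end`,
#'   `ring_ligands` (list column; `NA`/empty where a domain is absent).
#' @export
#' @examples
#' classify_sequence(strrep("A", 100))$sina_class  # modified_without_ring
classify_sequence <- function(sequence, motif = sina_ancestral_motif(),
                              max_mismatches = 0L,
                              ring_pattern = sina_ring_pattern()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || nchar(sequence) == 0L) {
    stop("cannot classify an empty sequence")
  }
  anc <- scan_degenerate(sequence, motif, max_mismatches)
  ring <- find_ring(sequence, ring_pattern)
  tibble::tibble(
    sina_class = sina_class_of(nrow(anc) > 0L, nrow(ring) > 0L),
    n_ancestral_hits = nrow(anc),
    ancestral_start = if (nrow(anc)) anc$start[1] else NA_integer_,
    ancestral_end = if (nrow(anc)) anc$end[1] else NA_integer_,
    ring_start = if (nrow(ring)) ring$start[1] else NA_integer_,
    ring_end = if (nrow(ring)) ring$end[1] else NA_integer_,
    ring_ligands = list(if (nrow(ring)) ring$ligand_pos[[1]] else integer())
  )
}

#' Classify every record of a proteome table
#'
#' @param proteins Data frame with `record_id`, `sequence` (and ideally
#'   `gene_id`); records should already have passed [apply_qc()].
#' @param collapse_isoforms If `TRUE`, the table must hold one record per
#'   gene (apply [select_isoforms()] first); duplicate `gene_id`s are an
#'   error. This matches per-gene counting; leave `FALSE` for a
#'   per-transcript audit.
#' @inheritParams classify_sequence
#' @return The input columns `record_id`, `gene_id` plus the per-record
#'   classification columns of [classify_sequence()].
#' @export
classify_proteins <- function(proteins, motif = sina_ancestral_motif(),
                              max_mismatches = 0L,
                              ring_pattern = sina_ring_pattern(),
                              collapse_isoforms = FALSE) {
  stopifnot(is.data.frame(proteins),
            all(c("record_id", "sequence") %in% names(proteins)))
  if (collapse_isoforms && "gene_id" %in% names(proteins) &&
      anyDuplicated(proteins$gene_id)) {
    stop("collapse_isoforms = TRUE but gene_id is duplicated: ",
         paste(unique(proteins$gene_id[duplicated(proteins$gene_id)]),
               collapse = ", "))
  }
  cls <- purrr::map_dfr(proteins$sequence, classify_sequence,
                        motif = motif, max_mismatches = max_mismatches,
                        ring_pattern = ring_pattern)
  ids <- tibble::tibble(
    record_id = proteins$record_id,
    gene_id = if ("gene_id" %in% names(proteins)) proteins$gene_id
              else proteins$record_id
  )
  dplyr::bind_cols(ids, cls)
}

#' Summarize per-record classes into a per-genome class-count row
#'
#' @param classified Output of [classify_proteins()].
#' @param species_tag,variety_tag Labels for the summary row.
#' @return A one-row tibble: `species_tag`, `variety_tag`, one count per
#'   class (in [sina_classes()] order) and `total`.
#' @export
summarize_genome <- function(classified, species_tag = "", variety_tag = "") {
  counts <- vapply(sina_classes(),
                   function(k) sum(classified$sina_class == k), integer(1))
  out <- tibble::as_tibble(as.list(counts))
  dplyr::bind_cols(
    tibble::tibble(species_tag = species_tag, variety_tag = variety_tag),
    out,
    tibble::tibble(total = sum(counts))
  )
}

#' Classify a proteome and summarize it in one step
#'
#' @inheritParams classify_proteins
#' @inheritParams summarize_genome
#' @return A list with `records` (per-record classification tibble) and
#'   `summary` (one-row genome summary).
#' @export
classify_genome <- function(proteins, motif = sina_ancestral_motif(),
                            max_mismatches = 0L,
                            ring_pattern = sina_ring_pattern(),
                            collapse_isoforms = FALSE,
                            species_tag = "", variety_tag = "") {
  if (nrow(proteins) == 0L) {
    records <- tibble::tibble(record_id = character(), gene_id = character(),
                              sina_class = character())
    return(list(records = records,
                summary = summarize_genome(records, species_tag, variety_tag)))
  }
  records <- classify_proteins(proteins, motif, max_mismatches, ring_pattern,
                               collapse_isoforms)
  list(records = records,
       summary = summarize_genome(records, species_tag, variety_tag))
}

#' Pool genome summaries across species
#'
#' Element-wise sums of the four class counts over many genome summary
#' rows, plus the grand total.
#'
#' @param summaries A tibble of genome summary rows ([summarize_genome()]),
#'   possibly empty.
#' @return A one-row tibble with the four pooled class counts and `total`.
#' @export
#' @examples
#' # pooled counts 784 + 72 + 2553 + 1447 give a grand total of 4856
aggregate_summaries <- function(summaries) {
  cols <- c(sina_classes(), "total")
  if (is.null(summaries) || nrow(summaries) == 0L) {
    return(tibble::as_tibble(as.list(stats::setNames(rep(0L, 5L), cols))))
  }
  tibble::as_tibble(lapply(summaries[cols], function(x) sum(as.integer(x))))
}
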