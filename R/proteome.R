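#' Read an amino-acid FASTA file into a protein table
#'
#' One row per FASTA entry. The header token before the first whitespace
#' becomes `record_id`; sequences are uppercased; input order is preserved.
#' Gene and isoform identity are derived from `record_id` under the chosen
#' ID scheme (see [parse_record_id()]).
#'
#' @param path Path to an amino-acid FASTA file.
#' @param scheme ID-parsing scheme passed to [parse_record_id()].
#' @param id_regex Custom regex for `scheme = "custom_regex"`.
#' @param species_tag,variety_tag Provenance tags attached to every record.
#' @return A tibble with columns `record_id`, `gene_id`, `isoform_label`,
#'   `chromosome`, `sequence`, `species_tag`, `variety_tag`.
#' @export
read_protein_fasta <- function(path, scheme = "dot_suffix", id_regex = NULL,
                               species_tag = "", variety_tag = "") {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate record_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parsed <- parse_record_id(ids, scheme = scheme, id_regex = id_regex)
  tibble::tibble(
    record_id = ids,
    gene_id = parsed$gene_id,
    isoform_label = parsed$isoform_label,
    chromosome = parsed$chromosome,
    sequence = unname(toupper(as.character(aa))),
    species_tag = species_tag,
    variety_tag = variety_tag
  )
}

#' Write a protein table to FASTA
#'
#' @param proteins Data frame with `record_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$record_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Parse record identifiers into gene and isoform labels
#'
#' Under the `dot_suffix` scheme the gene id is the substring before the
#' last `"."` and the isoform label the substring after it; identifiers
#' without a dot get isoform label `"1"`. Wheat-style identifiers
#' (`TraesCS1A03G0357800.2`) additionally yield the chromosome token
#' (`"1A"`) encoded in the gene stem. A `custom_regex` scheme takes a
#' regular expression with capture groups 1 = gene, 2 = isoform
#' (optionally 3 = chromosome).
#'
#' @param record_id Character vector of identifiers.
#' @param scheme One of `"dot_suffix"`, `"custom_regex"`.
#' @param id_regex Regex for `scheme = "custom_regex"`.
#' @return A tibble with `record_id`, `gene_id`, `isoform_label`,
#'   `chromosome` (`NA` where none is encoded).
#' @export
#' @examples
#' parse_record_id("TraesCS1A03G0357800.2")
#' parse_record_id("AT2G41980.1")
parse_record_id <- function(record_id, scheme = c("dot_suffix", "custom_regex"),
                            id_regex = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "dot_suffix") {
    has_dot <- grepl(".", record_id, fixed = TRUE)
    gene_id <- ifelse(has_dot, sub("\\.[^.]*$", "", record_id), record_id)
    isoform <- ifelse(has_dot, sub("^.*\\.", "", record_id), "1")
    chrom <- ifelse(
      grepl("^Traes[A-Za-z]{2}\\d[A-DU]", gene_id),
      sub("^Traes[A-Za-z]{2}(\\d[A-DU]).*$", "\\1", gene_id),
      NA_character_
    )
  } else {
    if (is.null(id_regex)) stop("custom_regex scheme requires id_regex")
    m <- regexec(id_regex, record_id)
    bad <- vapply(m, function(x) x[1] < 0, logical(1))
    if (any(bad)) {
      stop("id_regex does not match: ",
           paste(record_id[bad], collapse = ", "))
    }
    parts <- regmatches(record_id, m)
    gene_id <- vapply(parts, `[`, character(1), 2)
    isoform <- vapply(parts, function(x) {
      if (length(x) >= 3 && !is.na(x[3]) && nzchar(x[3])) x[3] else "1"
    }, character(1))
    chrom <- vapply(parts, function(x) {
      if (length(x) >= 4 && nzchar(x[4])) x[4] else NA_character_
    }, character(1))
  }
  tibble::tibble(
    record_id = record_id,
    gene_id = gene_id,
    isoform_label = isoform,
    chromosome = chrom
  )
}

#' Quality-control screen for protein sequences
#'
#' Applies the screening rule used when assembling the family: sequences
#' must start with methionine and contain no unknown residue (`X`).
#' A trailing `"*"` stop symbol is stripped before screening. Rejection
#' reasons are reported with fixed priority
#' `empty_sequence > non_met_start > unknown_residue` so reports are
#' deterministic.
#'
#' @param proteins Data frame with `record_id` and `sequence`.
#' @return A tibble `record_id`, `sequence` (stop-stripped, uppercased),
#'   `kept` (logical), `reason` (`NA` when kept). The kept/rejected rows
#'   partition the input.
#' @seealso [qc_filter()] for the kept records only.
#' @export
apply_qc <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("record_id", "sequence") %in% names(proteins)))
  seq <- sub("\\*$", "", toupper(proteins$sequence))
  reason <- dplyr::case_when(
    nchar(seq) == 0L ~ "empty_sequence",
    substr(seq, 1, 1) != "M" ~ "non_met_start",
    grepl("X", seq, fixed = TRUE) ~ "unknown_residue",
    TRUE ~ NA_character_
  )
  out <- proteins
  out$sequence <- seq
  out$kept <- is.na(reason)
  out$reason <- reason
  tibble::as_tibble(out)
}

#' Keep only QC-passing records
#'
#' @inheritParams apply_qc
#' @return The QC-passing rows of `proteins`, sequences stop-stripped.
#' @export
qc_filter <- function(proteins) {
  rep <- apply_qc(proteins)
  dplyr::select(dplyr::filter(rep, .data$kept), -"kept", -"reason")
}

#' Write a QC report as a tab-separated table
#'
#' @param qc Output of [apply_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  tab <- tibble::tibble(
    record_id = qc$record_id,
    status = ifelse(qc$kept, "kept", "rejected"),
    reason = ifelse(qc$kept, "", qc$reason)
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Default isoform scorer: number of in-scope domains
#'
#' Counts how many of the two diagnostic domains — the ancestral SINA motif
#' and the canonical RING domain — are detected in a sequence (0, 1 or 2).
#' Stands in for an external domain-scanner motif count when selecting a
#' representative isoform.
#'
#' @param sequence Amino-acid string.
#' @param motif A `degenerate_motif`.
#' @param max_mismatches Passed to [scan_degenerate()].
#' @param ring_pattern Passed to [find_ring()].
#' @return Integer domain count.
#' @export
score_domains <- function(sequence, motif = sina_ancestral_motif(),
                          max_mismatches = 0L,
                          ring_pattern = sina_ring_pattern()) {
  (nrow(scan_degenerate(sequence, motif, max_mismatches)) > 0L) +
    (nrow(find_ring(sequence, ring_pattern)) > 0L)
}

#' Select one representative isoform per gene
#'
#' For each gene, keeps the isoform with the maximal domain score
#' (the screened-transcript rule: the isoform carrying the maximum number
#' of detected motifs is retained). Ties are broken by the
#' lexicographically smallest isoform label, so selection is deterministic
#' and independent of input order.
#'
#' @param proteins Data frame with `record_id`, `gene_id`, `isoform_label`,
#'   `sequence`.
#' @param scorer Function mapping a sequence to a non-negative integer
#'   evidence count; default [score_domains()].
#' @return One row per gene: the selected records with a `domain_score`
#'   column recording the winning score.
#' @export
select_isoforms <- function(proteins, scorer = score_domains) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L,
            all(c("record_id", "gene_id", "isoform_label", "sequence") %in%
                  names(proteins)))
  scored <- dplyr::mutate(
    proteins,
    domain_score = vapply(.data$sequence, function(s) as.integer(scorer(s)),
                          integer(1), USE.NAMES = FALSE)
  )
  out <- scored |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$domain_score), .data$isoform_label,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  # preserve first-appearance gene order of the input
  out[match(unique(proteins$gene_id), out$gene_id), ]
}
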