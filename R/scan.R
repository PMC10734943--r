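#' Scan a sequence for a degenerate motif
#'
#' Slides the motif along the sequence and reports every window that
#' violates at most `max_mismatches` position classes. Wildcard positions
#' never count as mismatches; residues outside the 20-letter alphabet
#' (e.g. `X`) count as mismatches against any non-wildcard class.
#' Overlapping matches are all reported, in ascending start order.
#'
#' @param sequence A single amino-acid string (case-insensitive).
#' @param motif A `degenerate_motif` from [parse_consensus()].
#' @param max_mismatches Maximum number of violated position classes
#'   (default 0: the consensus already encodes variability through its
#'   wildcard positions).
#' @return A tibble with one row per match: `start`, `end` (1-based,
#'   inclusive), `mismatches`, `segment`.
#' @export
#' @examples
#' scan_degenerate("AAHLLADAA", parse_consensus("HL2XD/H"))
scan_degenerate <- function(sequence, motif, max_mismatches = 0L) {
  stopifnot(inherits(motif, "degenerate_motif"), max_mismatches >= 0)
  seq <- toupper(sequence)
  L <- nchar(seq)
  m <- motif$length
  empty <- tibble::tibble(
    start = integer(), end = integer(),
    mismatches = integer(), segment = character()
  )
  if (L < m) return(empty)
  chars <- strsplit(seq, "")[[1]]
  nw <- L - m + 1L
  mm <- integer(nw)
  for (j in seq_len(m)) {
    if (motif$wildcard[j]) next
    mm <- mm + !(chars[j:(j + nw - 1L)] %in% motif$classes[[j]])
  }
  hits <- which(mm <= max_mismatches)
  if (length(hits) == 0L) return(empty)
  tibble::tibble(
    start = hits,
    end = hits + m - 1L,
    mismatches = mm[hits],
    segment = substring(seq, hits, hits + m - 1L)
  )
}

#' Scan a proteome table for a degenerate motif
#'
#' Data-frame interface to [scan_degenerate()]: scans the `sequence` column
#' of a protein table and binds the per-record match tables.
#'
#' @param proteins A data frame with at least `record_id` and `sequence`.
#' @param motif A `degenerate_motif` (default: the ancestral SINA motif).
#' @param max_mismatches Passed to [scan_degenerate()].
#' @return A tibble with columns `record_id`, `start`, `end`, `mismatches`,
#'   `segment`; zero rows for records without a match.
#' @export
scan_motif <- function(proteins, motif = sina_ancestral_motif(),
                       max_mismatches = 0L) {
  stopifnot(is.data.frame(proteins),
            all(c("record_id", "sequence") %in% names(proteins)))
  purrr::map2_dfr(proteins$record_id, proteins$sequence, function(id, s) {
    hits <- scan_degenerate(s, motif, max_mismatches)
    if (nrow(hits) == 0L) return(hits[0, ])
    dplyr::bind_cols(tibble::tibble(record_id = id), hits)
  })
}

# Wrap the 8 anchor tokens (residue literals / bracket classes not followed
# by a bounded quantifier) of a RING-style expression in capture groups so
# the metal-ligand offsets fall out of the PCRE match. "[C,H]" is
# normalized to "[CH]": commas cannot occur in protein sequences.
ring_anchor_regex <- function(pattern) {
  pat <- pattern
  out <- character()
  i <- 1L
  n <- nchar(pat)
  while (i <= n) {
    ch <- substr(pat, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pat, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced '[' in RING pattern")
      # commas inside a residue class are presentational: [C,H] means {C,H}
      tok <- gsub(",", "", substr(pat, i, i + j - 1L), fixed = TRUE)
      i <- i + j
    } else {
      tok <- ch
      i <- i + 1L
    }
    quant <- ""
    if (i <= n && substr(pat, i, i) == "{") {
      j <- regexpr("}", substr(pat, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced '{' in RING pattern")
      quant <- substr(pat, i, i + j - 1L)
      i <- i + j
    }
    out <- c(out, if (quant == "") paste0("(", tok, ")") else paste0(tok, quant))
  }
  paste(out, collapse = "")
}

#' Locate a canonical RING domain
#'
#' Matches the canonical RING zinc-finger expression against a sequence and
#' returns the leftmost occurrence under standard greedy bounded quantifiers
#' with backtracking, together with the offsets of the eight metal-ligand
#' residues (the octet C-C-C-H-\[C/H\]-C-C-C).
#'
#' @param sequence A single amino-acid string (case-insensitive).
#' @param pattern RING regular expression; default [sina_ring_pattern()].
#'   The eight positions written without a bounded quantifier are treated as
#'   the metal-ligand anchors.
#' @param all If `TRUE`, exhaustively report every distinct match window
#'   (one leftmost-anchored match per feasible start offset) instead of only
#'   the leftmost.
#' @return A tibble with zero rows (no RING) or one row per match:
#'   `start`, `end` (1-based, inclusive), `ligand_pos` (list column of 8
#'   strictly increasing offsets), `ligand_res` (8-letter string).
#' @export
#' @examples
#' find_ring("CAACAAAAAAAAACAAAHAACAACAAAACAAC")
find_ring <- function(sequence, pattern = sina_ring_pattern(), all = FALSE) {
  seq <- toupper(sequence)
  rx <- ring_anchor_regex(pattern)
  empty <- tibble::tibble(
    start = integer(), end = integer(),
    ligand_pos = list(), ligand_res = character()
  )
  one <- function(rx_use, offset) {
    m <- regexpr(rx_use, substr(seq, offset, nchar(seq)), perl = TRUE)
    if (m < 0) return(NULL)
    cs <- as.integer(attr(m, "capture.start")) + offset - 1L
    start <- as.integer(m) + offset - 1L
    end <- start + attr(m, "match.length") - 1L
    tibble::tibble(
      start = start, end = end,
      ligand_pos = list(cs),
      ligand_res = paste(substring(seq, cs, cs), collapse = "")
    )
  }
  if (!all) {
    res <- one(rx, 1L)
    return(if (is.null(res)) empty else res)
  }
  rx_anchored <- paste0("^", rx)
  out <- list()
  for (s in seq_len(nchar(seq))) {
    res <- one(rx_anchored, s)
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0L) return(empty)
  dplyr::distinct(dplyr::bind_rows(out), .data$start, .data$end,
                  .keep_all = TRUE)
}

#' Scan a proteome table for RING domains
#'
#' @param proteins A data frame with `record_id` and `sequence` columns.
#' @inheritParams find_ring
#' @return A tibble of RING matches with a leading `record_id` column;
#'   records without a RING domain contribute no rows.
#' @export
scan_ring <- function(proteins, pattern = sina_ring_pattern(), all = FALSE) {
  stopifnot(is.data.frame(proteins),
            base::all(c("record_id", "sequence") %in% names(proteins)))
  purrr::map2_dfr(proteins$record_id, proteins$sequence, function(id, s) {
    hits <- find_ring(s, pattern, all = all)
    if (nrow(hits) == 0L) return(hits[0, ])
    dplyr::bind_cols(tibble::tibble(record_id = id), hits)
  })
}
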