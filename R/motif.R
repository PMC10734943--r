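#' @keywords internal
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' The ancestral SINA consensus pattern
#'
#' The degenerate 58-residue consensus distilled from the conserved core of
#' the SINA-domain motif shared by phylogenetically ancestral SINA proteins
#' across plants. In the pattern grammar `X` stands for any amino acid,
#' a digit repeats the preceding unit, and `D/H` denotes a position that
#' accepts either residue.
#'
#' @return A single string, the default consensus pattern.
#' @seealso [parse_consensus()] to turn it into a scannable motif.
#' @export
#' @examples
#' sina_consensus_pattern()
sina_consensus_pattern <- function() {
  "HL2XD/HXV4XG2XFXHRYV9XAXWMLT3XCXG2XFXLXFEAFXL3XP"
}

#' The canonical RING zinc-finger pattern
#'
#' Regular expression matching H2- and HC-type RING domains through their
#' eight metal-ligand residues (the octet C-C-C-H-\[C/H\]-C-C-C) at the
#' canonical inter-ligand spacings. `[C,H]` is read as the residue class
#' \{C, H\}; the comma is presentational.
#'
#' @return A single string, the default RING regular expression.
#' @seealso [find_ring()]
#' @export
sina_ring_pattern <- function() {
  "C[A-Z]{2}C[A-Z]{9,39}C[A-Z]{3,9}H[A-Z]{2,3}[C,H][A-Z]{2}C[A-Z]{4,48}C[A-Z]{2}C"
}

#' Parse a degenerate protein consensus pattern
#'
#' Parses the compact consensus grammar used for the ancestral SINA motif
#' into an explicit position-class representation. Grammar: a unit is a
#' residue letter or a two-letter alternative `A/B`; an integer following a
#' unit repeats it that many times; the letter `X` is a wildcard matching
#' any residue.
#'
#' @param pattern A single pattern string, e.g. `"HL2XD/H"`.
#' @return An object of class `degenerate_motif`: a list with elements
#'   `classes` (one character vector of allowed residues per position,
#'   `NA` for wildcard), `wildcard` (logical per position), `length`,
#'   and `pattern` (the source string).
#' @export
#' @examples
#' m <- parse_consensus("HL2XD/H")
#' m$length  # 5
#' parse_consensus(sina_consensus_pattern())
parse_consensus <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  chars <- strsplit(toupper(pattern), "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty consensus pattern")
  # residue letters: A-Z minus the wildcard letter, so ambiguity codes
  # (B, Z, ...) are usable, mirroring the [A-Z] classes of the RING pattern
  residue_ok <- setdiff(LETTERS, "X")
  classes <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (!ch %in% LETTERS) {
      stop(sprintf("illegal character '%s' in consensus pattern at offset %d", ch, i))
    }
    unit <- ch
    i <- i + 1L
    if (i <= n && chars[i] == "/") {
      if (i + 1L > n || !chars[i + 1L] %in% residue_ok) {
        stop(sprintf("dangling '/' in consensus pattern at offset %d", i))
      }
      if (unit == "X") {
        stop(sprintf("wildcard 'X' cannot appear in an alternative at offset %d", i - 1L))
      }
      unit <- c(unit, chars[i + 1L])
      i <- i + 2L
    }
    rep_n <- 1L
    if (i <= n && grepl("[0-9]", chars[i])) {
      digits <- character()
      while (i <= n && grepl("[0-9]", chars[i])) {
        digits <- c(digits, chars[i])
        i <- i + 1L
      }
      rep_n <- as.integer(paste(digits, collapse = ""))
      if (rep_n == 0L) {
        stop(sprintf("repeat count 0 in consensus pattern at offset %d", i - length(digits)))
      }
    }
    cls <- if (identical(unit, "X")) NA_character_ else unit
    classes <- c(classes, rep(list(cls), rep_n))
  }
  wildcard <- vapply(classes, function(x) length(x) == 1L && is.na(x[1]), logical(1))
  structure(
    list(
      classes = classes,
      wildcard = wildcard,
      length = length(classes),
      pattern = pattern
    ),
    class = "degenerate_motif"
  )
}

#' The parsed ancestral SINA motif
#'
#' Convenience wrapper: [sina_consensus_pattern()] run through
#' [parse_consensus()].
#'
#' @return A `degenerate_motif`.
#' @export
sina_ancestral_motif <- function() parse_consensus(sina_consensus_pattern())

#' @export
#' @method format degenerate_motif
format.degenerate_motif <- function(x, ...) {
  # canonical re-serialization: run-length over identical position classes
  keys <- vapply(seq_len(x$length), function(i) {
    if (x$wildcard[i]) "X" else paste(sort(x$classes[[i]]), collapse = "/")
  }, character(1))
  r <- rle(keys)
  paste0(r$values, ifelse(r$lengths > 1L, r$lengths, ""), collapse = "")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  n_fixed <- sum(!x$wildcard & lengths(x$classes) == 1L)
  n_alt <- sum(!x$wildcard & lengths(x$classes) > 1L)
  cat("<degenerate_motif> length", x$length,
      sprintf("(%d fixed, %d alternative, %d wildcard)\n",
              n_fixed, n_alt, sum(x$wildcard)))
  cat("  pattern:  ", x$pattern, "\n", sep = "")
  cat("  canonical:", format(x), "\n", sep = " ")
  invisible(x)
}

#' Per-window match probability of a degenerate motif
#'
#' Probability that a window of i.i.d. residues drawn from
#' `residue_frequencies` satisfies every position class of the motif:
#' the product over positions of the summed frequency of the allowed class,
#' with wildcards contributing 1. Used as the analytic null for
#' false-positive calibration of [scan_degenerate()].
#'
#' @param motif A `degenerate_motif`.
#' @param residue_frequencies Named numeric vector of residue frequencies
#'   over the 20-letter alphabet, summing to 1 (default uniform).
#' @return A single probability.
#' @export
#' @examples
#' match_probability(parse_consensus("X"))   # 1
#' match_probability(parse_consensus("C"))   # 0.05
match_probability <- function(motif, residue_frequencies = NULL) {
  stopifnot(inherits(motif, "degenerate_motif"))
  if (is.null(residue_frequencies)) {
    residue_frequencies <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (any(residue_frequencies < 0)) stop("negative residue frequency")
  if (abs(sum(residue_frequencies) - 1) > 1e-9) {
    stop("residue frequencies must sum to 1")
  }
  p <- 1
  for (i in seq_len(motif$length)) {
    if (motif$wildcard[i]) next
    p <- p * sum(residue_frequencies[motif$classes[[i]]])
  }
  unname(p)
}
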