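#' Read gene loci from GFF3 or a tab-separated table
#'
#' Loads gene coordinates and assigns each gene its ordinal rank along its
#' chromosome (sorted by ascending start). Family membership is set from a
#' supplied id vector. For GFF3 input only `gene` features are used
#' (mRNA/CDS children are ignored); coordinates are 1-based inclusive.
#'
#' @param source Path to a GFF3 file (`.gff`/`.gff3`) or a tab-separated
#'   table with columns `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @param family_ids Character vector of family-member gene ids.
#' @return A tibble: `gene_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `strand`, `is_family_member`, `rank`.
#' @export
read_loci <- function(source, family_ids = character()) {
  if (grepl("\\.gff3?$", source, ignore.case = TRUE)) {
    df <- as.data.frame(rtracklayer::import(source))
    df <- df[df$type == "gene", , drop = FALSE]
    ids <- if (!is.null(df$gene_id)) df$gene_id else df$ID
    tab <- tibble::tibble(
      gene_id = as.character(ids),
      chromosome = as.character(df$seqnames),
      start = as.integer(df$start),
      end = as.integer(df$end),
      strand = as.character(df$strand)
    )
  } else {
    tab <- readr::read_tsv(source, show_col_types = FALSE,
                           col_types = readr::cols(
                             gene_id = "c", chromosome = "c",
                             start = "i", end = "i", strand = "c"
                           ))
  }
  if (nrow(tab) == 0L) {
    return(tibble::tibble(gene_id = character(), chromosome = character(),
                          start_bp = integer(), end_bp = integer(),
                          strand = character(), is_family_member = logical(),
                          rank = integer()))
  }
  if (any(tab$end < tab$start)) {
    stop("locus with end < start: ",
         paste(tab$gene_id[tab$end < tab$start], collapse = ", "))
  }
  if (!all(tab$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(unique(setdiff(tab$strand, c("+", "-"))), collapse = ", "))
  }
  tab |>
    dplyr::rename(start_bp = "start", end_bp = "end") |>
    dplyr::mutate(is_family_member = .data$gene_id %in% family_ids) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

# one-decimal percentage, truncated by default (58.865% prints as 58.8)
pct_1dp <- function(count, total, truncate = TRUE) {
  p <- 100 * count / total
  if (truncate) trunc(p * 10) / 10 else round(p, 1)
}

#' Chromosomal distribution of a gene family
#'
#' Per-chromosome family counts and percentages of the family total.
#' Percentages are truncated (not rounded) to one decimal by default,
#' matching the reporting convention for figures like 83/141 = 58.8%.
#'
#' @param loci Locus tibble from [read_loci()].
#' @param truncate Truncate (default) rather than round percentages.
#' @return A tibble `chromosome`, `n`, `pct`, with the family total in
#'   attribute `"family_total"`; counts sum to the family total.
#' @export
gene_distribution <- function(loci, truncate = TRUE) {
  fam <- dplyr::filter(loci, .data$is_family_member)
  total <- nrow(fam)
  out <- fam |>
    dplyr::count(.data$chromosome, name = "n") |>
    dplyr::mutate(pct = pct_1dp(.data$n, total, truncate))
  attr(out, "family_total") <- total
  out
}

#' Percentage of the family carried by a chromosome group
#'
#' @param loci Locus tibble from [read_loci()].
#' @param chromosomes Chromosomes to pool (e.g. the homoeologous group
#'   `c("3A", "3B", "3D")`).
#' @param truncate Truncate (default) rather than round.
#' @return A one-row tibble `n`, `family_total`, `pct`.
#' @export
chrom_group_pct <- function(loci, chromosomes, truncate = TRUE) {
  fam <- dplyr::filter(loci, .data$is_family_member)
  n <- sum(fam$chromosome %in% chromosomes)
  tibble::tibble(n = n, family_total = nrow(fam),
                 pct = pct_1dp(n, nrow(fam), truncate))
}

#' Expected percentage under a uniform chromosomal distribution
#'
#' The share of a gene family expected on a focal set of chromosomes if
#' genes were distributed at random among all chromosomes: e.g. 3 of 21
#' wheat chromosomes gives 14.29%, displayed as 14%.
#'
#' @param n_focal_chromosomes Number of focal chromosomes.
#' @param n_chromosomes Total number of chromosomes (>= 1).
#' @return A one-row tibble `pct` (exact) and `display` (integer, round
#'   half up).
#' @export
#' @examples
#' uniform_expectation(3, 21)
uniform_expectation <- function(n_focal_chromosomes, n_chromosomes) {
  if (n_chromosomes == 0) stop("n_chromosomes must be >= 1")
  stopifnot(n_focal_chromosomes >= 0, n_focal_chromosomes <= n_chromosomes)
  pct <- 100 * n_focal_chromosomes / n_chromosomes
  tibble::tibble(pct = pct, display = floor(pct + 0.5))
}

#' Detect tandem-duplication clusters
#'
#' Per chromosome, finds the maximal runs of two or more family genes in
#' which each consecutive pair is separated by at most `max_intervening`
#' non-family genes in gene-rank order ("contiguous or tandem genes,
#' sometimes separated by one or a few other genes"). Adjacency is by gene
#' rank, not physical distance, so the result is invariant to non-family
#' coordinates as long as gene order is unchanged.
#'
#' @param loci Locus tibble from [read_loci()].
#' @param max_intervening Maximum number of intervening non-family genes
#'   between consecutive cluster members (default 1).
#' @return A tibble with one row per cluster: `chromosome`, `cluster_id`,
#'   `size`, `members` (list of gene ids sorted by start), `intervening`
#'   (list of per-gap non-family gene counts), `start_bp`, `end_bp`,
#'   `span_bp`.
#' @export
detect_clusters <- function(loci, max_intervening = 1L) {
  stopifnot(max_intervening >= 0)
  fam <- loci |>
    dplyr::filter(.data$is_family_member) |>
    dplyr::arrange(.data$chromosome, .data$rank)
  out <- list()
  for (chr in unique(fam$chromosome)) {
    f <- fam[fam$chromosome == chr, ]
    if (nrow(f) < 2L) next
    gaps <- diff(f$rank) - 1L
    run_id <- cumsum(c(0L, gaps > max_intervening))
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      if (length(idx) < 2L) next
      g <- f[idx, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        chromosome = chr,
        size = nrow(g),
        members = list(g$gene_id),
        intervening = list(diff(g$rank) - 1L),
        start_bp = min(g$start_bp),
        end_bp = max(g$end_bp),
        span_bp = max(g$end_bp) - min(g$start_bp)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chromosome = character(), cluster_id = integer(),
                          size = integer(), members = list(),
                          intervening = list(), start_bp = integer(),
                          end_bp = integer(), span_bp = integer()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::relocate(dplyr::mutate(res, cluster_id = dplyr::row_number()),
                  "cluster_id", .after = "chromosome")
}

#' Span of a genomic region
#'
#' Length of a coordinate interval in bp and Mb. The span is the coordinate
#' difference `end - start`, which reproduces reported region sizes such as
#' 1.26 Mb for 32273198..33537271; the 1 bp difference to an
#' inclusive-length convention is immaterial at Mb scale.
#'
#' @param start_bp,end_bp 1-based coordinates, `end_bp >= start_bp`.
#' @return A one-row tibble `bp` and `mb` (rounded to two decimals).
#' @export
#' @examples
#' region_span(32273198, 33537271)
region_span <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) stop("end_bp must be >= start_bp")
  bp <- end_bp - start_bp
  tibble::tibble(bp = bp, mb = round(bp / 1e6, 2))
}
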