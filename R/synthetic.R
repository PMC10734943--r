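sample_residues <- function(n, freqs = NULL) {
  if (is.null(freqs)) {
    sample(AA_ALPHABET, n, replace = TRUE)
  } else {
    sample(names(freqs), n, replace = TRUE, prob = freqs)
  }
}

# one concrete realization of a degenerate motif: fixed positions exact,
# alternative positions pick one member, wildcards sampled from background
realize_motif <- function(motif, freqs = NULL) {
  vapply(seq_len(motif$length), function(i) {
    if (motif$wildcard[i]) sample_residues(1L, freqs)
    else if (length(motif$classes[[i]]) == 1L) motif$classes[[i]]
    else sample(motif$classes[[i]], 1L)
  }, character(1))
}

# minimal-width RING realization: the 8 metal ligands at the tightest
# canonical spacings (2,9,3,2,2,4,2), spacers drawn from residues other
# than C and H so the planted segment itself stays unambiguous
realize_ring <- function() {
  spacer <- function(n) sample(setdiff(AA_ALPHABET, c("C", "H")), n,
                               replace = TRUE)
  c("C", spacer(2), "C", spacer(9), "C", spacer(3), "H", spacer(2),
    sample(c("C", "H"), 1), spacer(2), "C", spacer(4), "C", spacer(2), "C")
}

RING_MIN_WIDTH <- 32L

#' Generate one synthetic protein with a known class
#'
#' Samples a background sequence from the configured residue frequencies
#' (uniform over the 20 amino acids by default), then plants a concrete
#' realization of the ancestral SINA motif and/or a minimal RING-satisfying
#' segment according to the requested class. The first residue is fixed to
#' methionine so generated records pass [apply_qc()]. Background draws are
#' rejected and resampled until the only ancestral-motif hit and the only
#' RING match window are the planted ones (none for `modified_without_ring`),
#' so the planted class is exactly recoverable; the loop is capped at 1000
#' attempts. Deterministic per seed.
#'
#' @param class_label One of [sina_classes()].
#' @param length Sequence length; must accommodate the planted features
#'   (motif length + minimal RING width + 10 when both are planted).
#' @param seed Integer seed (required).
#' @param motif A `degenerate_motif` to plant (default ancestral SINA).
#' @param freqs Optional named residue-frequency vector for the background.
#' @return A list with `record` (one-row protein tibble) and `truth`
#'   (one-row tibble: `record_id`, `class`, `motif_start`, `motif_end`,
#'   `ring_start`, `ring_end`).
#' @export
make_protein <- function(class_label, length, seed,
                         motif = sina_ancestral_motif(), freqs = NULL) {
  stopifnot(class_label %in% sina_classes(), !missing(seed))
  len <- as.integer(length)
  rm(length)  # unshadow base::length
  want_motif <- startsWith(class_label, "ancestral")
  want_ring <- endsWith(class_label, "_with_ring")
  need <- 1L + (if (want_motif) motif$length else 0L) +
    (if (want_ring) RING_MIN_WIDTH else 0L) +
    (if (want_motif && want_ring) 10L else 0L)
  if (len < need) {
    stop(sprintf("length %d infeasible for class %s (needs >= %d)",
                 len, class_label, need))
  }
  withr::local_seed(seed)
  for (attempt in seq_len(1000L)) {
    chars <- sample_residues(len, freqs)
    chars[1] <- "M"
    # choose non-overlapping planting offsets in 2..len
    slots <- integer(0)
    widths <- c(if (want_motif) motif$length, if (want_ring) RING_MIN_WIDTH)
    if (length(widths) > 0) {
      ok <- FALSE
      for (try in seq_len(50L)) {
        starts <- vapply(widths, function(w) {
          sample(2:(len - w + 1L), 1L)
        }, integer(1))
        ends <- starts + widths - 1L
        if (length(starts) == 1L ||
            (starts[2] > ends[1] || ends[2] < starts[1])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next
      slots <- starts
    }
    motif_at <- if (want_motif) slots[1] else NA_integer_
    ring_at <- if (want_ring) slots[length(slots)] else NA_integer_
    if (want_motif) {
      chars[motif_at:(motif_at + motif$length - 1L)] <- realize_motif(motif, freqs)
    }
    if (want_ring) {
      chars[ring_at:(ring_at + RING_MIN_WIDTH - 1L)] <- realize_ring()
    }
    seq <- paste(chars, collapse = "")
    # verify truth-table closure: detectors fire exactly at planted sites
    hits <- scan_degenerate(seq, motif, 0L)
    motif_ok <- if (want_motif) {
      nrow(hits) == 1L && hits$start == motif_at
    } else nrow(hits) == 0L
    if (!motif_ok) next
    ring_hits <- find_ring(seq, all = TRUE)
    ring_ok <- if (want_ring) {
      nrow(ring_hits) >= 1L && all(ring_hits$start == ring_at)
    } else nrow(ring_hits) == 0L
    if (!ring_ok) next
    record <- tibble::tibble(
      record_id = sprintf("syn_%s_%d.1", class_label, seed),
      gene_id = sprintf("syn_%s_%d", class_label, seed),
      isoform_label = "1",
      chromosome = NA_character_,
      sequence = seq,
      species_tag = "synthetic",
      variety_tag = ""
    )
    truth <- tibble::tibble(
      record_id = record$record_id,
      class = class_label,
      motif_start = motif_at,
      motif_end = if (want_motif) motif_at + motif$length - 1L else NA_integer_,
      ring_start = ring_at,
      ring_end = if (want_ring) ring_at + RING_MIN_WIDTH - 1L else NA_integer_
    )
    return(list(record = record, truth = truth))
  }
  stop("failed to generate a clean synthetic protein in 1000 attempts")
}

#' Generate a synthetic proteome with a known class mix
#'
#' Batch wrapper over [make_protein()] with unique record ids. Default
#' lengths are drawn from 250-420 aa, bracketing the average length
#' observed for wheat SINA proteins (about 334 aa).
#'
#' @param class_mix Named integer vector of record counts per class
#'   (names from [sina_classes()]; missing classes mean 0).
#' @param length_range Length range `c(min, max)` to sample from.
#' @param seed Integer seed (required).
#' @param fasta,truth_file Optional output paths for the FASTA file and
#'   the tab-separated truth table.
#' @inheritParams make_protein
#' @return A list with `proteins` (protein tibble) and `truth`
#'   (per-record truth tibble).
#' @export
#' @examples
#' p <- make_proteome(c(ancestral_with_ring = 2, modified_without_ring = 3),
#'                    seed = 1)
#' nrow(p$proteins)  # 5
make_proteome <- function(class_mix, length_range = c(250L, 420L), seed,
                          motif = sina_ancestral_motif(), freqs = NULL,
                          fasta = NULL, truth_file = NULL) {
  stopifnot(!missing(seed), all(names(class_mix) %in% sina_classes()),
            all(class_mix >= 0))
  withr::local_seed(seed)
  labels <- rep(names(class_mix), class_mix)
  if (length(labels) == 0L) {
    proteins <- tibble::tibble(record_id = character(), gene_id = character(),
                               isoform_label = character(),
                               chromosome = character(), sequence = character(),
                               species_tag = character(),
                               variety_tag = character())
    truth <- tibble::tibble(record_id = character(), class = character(),
                            motif_start = integer(), motif_end = integer(),
                            ring_start = integer(), ring_end = integer())
  } else {
    lens <- sample(length_range[1]:length_range[2], length(labels),
                   replace = TRUE)
    sub_seeds <- sample.int(2^31 - 1L, length(labels))
    made <- purrr::pmap(list(labels, lens, sub_seeds, seq_along(labels)),
                        function(cl, len, s, i) {
      out <- make_protein(cl, len, s, motif = motif, freqs = freqs)
      out$record$record_id <- sprintf("syng%04d.1", i)
      out$record$gene_id <- sprintf("syng%04d", i)
      out$truth$record_id <- out$record$record_id
      out
    })
    proteins <- purrr::map_dfr(made, "record")
    truth <- purrr::map_dfr(made, "truth")
  }
  if (!is.null(fasta)) write_protein_fasta(proteins, fasta)
  if (!is.null(truth_file)) readr::write_tsv(truth, truth_file)
  list(proteins = proteins, truth = truth)
}

#' Generate a locus table with planted tandem clusters
#'
#' Emulates a chromosome layout of interleaved family and non-family genes:
#' clusters from `cluster_spec` are planted left to right (cycling over
#' chromosomes), with intra-cluster members separated by the specified
#' number of intervening non-family genes and clusters separated from each
#' other (and chromosome ends) by strictly more than
#' `detect_max_intervening` non-family genes, so [detect_clusters()] at
#' that threshold recovers exactly the planted clusters.
#'
#' @param n_chromosomes Number of chromosomes (`chr1`, `chr2`, ...).
#' @param genes_per_chromosome Total genes laid out per chromosome.
#' @param cluster_spec List of `c(size, intervening)` pairs: cluster size
#'   (>= 2) and the number of non-family genes between consecutive
#'   members (must be `<= detect_max_intervening`).
#' @param seed Integer seed (required).
#' @param detect_max_intervening Detection threshold the layout must defeat
#'   between clusters (default 1).
#' @return A list with `loci` (tibble as from [read_loci()]) and `truth`
#'   (tibble `gene_id`, `cluster_id`, `NA` for non-members).
#' @export
make_locus_table <- function(n_chromosomes = 3L, genes_per_chromosome = 60L,
                             cluster_spec = list(c(3L, 0L), c(2L, 1L)),
                             seed, detect_max_intervening = 1L) {
  stopifnot(!missing(seed))
  withr::local_seed(seed)
  sizes <- vapply(cluster_spec, `[`, integer(1), 1L)
  gaps_in <- vapply(cluster_spec, `[`, integer(1), 2L)
  stopifnot(all(sizes >= 2L), all(gaps_in >= 0L),
            all(gaps_in <= detect_max_intervening))
  chrom_of <- rep_len(seq_len(n_chromosomes), length(cluster_spec))
  # per-chromosome family slot positions (gene ranks)
  fam_slots <- vector("list", n_chromosomes)
  cluster_id_of <- vector("list", n_chromosomes)
  for (k in seq_along(cluster_spec)) {
    chr <- chrom_of[k]
    cursor <- if (length(fam_slots[[chr]]) == 0L) 0L
              else max(fam_slots[[chr]])
    # inter-cluster separation strictly beyond the detection threshold
    cursor <- cursor + detect_max_intervening + 2L +
      sample(0:3, 1L)
    members <- cursor + cumsum(c(0L, rep(gaps_in[k] + 1L, sizes[k] - 1L)))
    fam_slots[[chr]] <- c(fam_slots[[chr]], members)
    cluster_id_of[[chr]] <- c(cluster_id_of[[chr]], rep(k, sizes[k]))
  }
  out <- list()
  truth <- list()
  for (chr in seq_len(n_chromosomes)) {
    if (length(fam_slots[[chr]]) > 0 &&
        max(fam_slots[[chr]]) + detect_max_intervening + 1L >
        genes_per_chromosome) {
      stop("genes_per_chromosome too small for the requested clusters")
    }
    widths <- sample(1000:5000, genes_per_chromosome, replace = TRUE)
    gaps <- sample(5000:50000, genes_per_chromosome, replace = TRUE)
    starts <- cumsum(gaps) + c(0L, cumsum(widths))[seq_len(genes_per_chromosome)]
    ids <- sprintf("chr%d_g%03d", chr, seq_len(genes_per_chromosome))
    fam <- seq_len(genes_per_chromosome) %in% fam_slots[[chr]]
    out[[chr]] <- tibble::tibble(
      gene_id = ids,
      chromosome = paste0("chr", chr),
      start_bp = as.integer(starts),
      end_bp = as.integer(starts + widths),
      strand = sample(c("+", "-"), genes_per_chromosome, replace = TRUE),
      is_family_member = fam,
      rank = seq_len(genes_per_chromosome)
    )
    cl <- rep(NA_integer_, genes_per_chromosome)
    cl[fam_slots[[chr]]] <- cluster_id_of[[chr]]
    truth[[chr]] <- tibble::tibble(gene_id = ids, cluster_id = cl)
  }
  list(loci = dplyr::bind_rows(out), truth = dplyr::bind_rows(truth))
}

#' Simulate integer gene-count evolution on a random tree
#'
#' Generates a random rooted topology and evolves an integer count from the
#' root toward the leaves: on each edge, with probability
#' `change_probability`, the count steps by a uniform amount in
#' `1..max_step`, up or down (clipped at 0). The realized states at every
#' node and the total absolute change are recorded, so parsimony
#' reconstructions can be checked against the simulation
#' (`reconstruction cost <= total event weight`).
#'
#' @param n_leaves Number of leaves.
#' @param root_count Count at the root.
#' @param change_probability Per-edge probability of a change event.
#' @param max_step Maximum step magnitude per event.
#' @param seed Integer seed (required).
#' @return A list: `tree` (`phylo`), `leaf_counts` (named vector),
#'   `true_states` (integer per node, ape numbering), `n_events`,
#'   `event_weight` (total realized absolute change).
#' @export
make_count_tree <- function(n_leaves, root_count, change_probability = 0.3,
                            max_step = 3L, seed) {
  stopifnot(!missing(seed), n_leaves >= 2, root_count >= 0,
            change_probability >= 0, change_probability <= 1, max_step >= 1)
  withr::local_seed(seed)
  tree <- ape::rtree(n_leaves)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_leaves + tree$Nnode
  states <- rep(NA_integer_, n_node)
  states[n_leaves + 1L] <- root_count
  n_events <- 0L
  weight <- 0L
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    s <- states[parent]
    if (stats::runif(1) < change_probability) {
      step <- sample(seq_len(max_step), 1L) * sample(c(-1L, 1L), 1L)
      s2 <- max(0L, s + step)
      n_events <- n_events + 1L
      weight <- weight + abs(s2 - s)
      s <- s2
    }
    states[child] <- s
  }
  list(
    tree = tree,
    leaf_counts = stats::setNames(states[seq_len(n_leaves)], tree$tip.label),
    true_states = states,
    n_events = n_events,
    event_weight = weight
  )
}
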