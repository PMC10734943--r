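# Independent oracles the implementation is checked against.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# naive per-window motif checker: examines every window position by
# position, independently of the vectorized scanner
naive_scan <- function(sequence, motif, max_mismatches = 0L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  m <- motif$length
  if (length(chars) < m) return(integer())
  hits <- integer()
  for (s in seq_len(length(chars) - m + 1L)) {
    mm <- 0L
    for (j in seq_len(m)) {
      if (motif$wildcard[j]) next
      if (!chars[s + j - 1L] %in% motif$classes[[j]]) mm <- mm + 1L
    }
    if (mm <= max_mismatches) hits <- c(hits, s)
  }
  hits
}

# reference regular-expression engine for RING presence/absence: the TRE
# engine (perl = FALSE), fed the canonical pattern with the residue class
# written explicitly
RING_TRE <- "C[A-Z]{2}C[A-Z]{9,39}C[A-Z]{3,9}H[A-Z]{2,3}[CH][A-Z]{2}C[A-Z]{4,48}C[A-Z]{2}C"
tre_has_ring <- function(sequence) grepl(RING_TRE, toupper(sequence),
                                         perl = FALSE)

# exhaustive minimal parsimony cost: enumerates every integer assignment
# of the internal nodes over 0..max_state
brute_force_parsimony <- function(tree, leaf_counts, max_state,
                                  cost = c("linear", "squared")) {
  cost <- match.arg(cost)
  cost_fun <- if (cost == "linear") function(a, b) abs(a - b)
              else function(a, b) (a - b)^2
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  states <- 0:max_state
  grids <- do.call(expand.grid, rep(list(states), length(internal)))
  tip_states <- as.integer(leaf_counts[tree$tip.label])
  best <- Inf
  edges <- tree$edge
  for (i in seq_len(nrow(grids))) {
    assign <- c(tip_states, as.integer(grids[i, ]))
    total <- sum(cost_fun(assign[edges[, 1]], assign[edges[, 2]]))
    if (total < best) best <- total
  }
  best
}

# brute-force tandem-cluster finder: tests every contiguous window of
# family genes for the gap condition and keeps maximal windows
brute_force_clusters <- function(loci, max_intervening = 1L) {
  out <- list()
  for (chr in unique(loci$chromosome)) {
    f <- loci[loci$chromosome == chr & loci$is_family_member, ]
    f <- f[order(f$rank), ]
    nf <- nrow(f)
    if (nf < 2) next
    valid <- function(i, j) all(diff(f$rank[i:j]) - 1L <= max_intervening)
    for (i in seq_len(nf - 1L)) {
      for (j in (i + 1L):nf) {
        if (!valid(i, j)) next
        left_ext <- i > 1L && valid(i - 1L, j)
        right_ext <- j < nf && valid(i, j + 1L)
        if (!left_ext && !right_ext) {
          out[[length(out) + 1L]] <- list(chromosome = chr,
                                          members = f$gene_id[i:j])
        }
      }
    }
  }
  out
}

# independently-coded Dunn z (textbook formula, tie term from the sorted
# value runs rather than table())
dunn_oracle <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  lv <- levels(g)
  runs <- rle(sort(x))$lengths
  ties <- sum(runs^3 - runs)
  s2 <- (n * (n + 1) / 12) - ties / (12 * (n - 1))
  res <- list()
  for (a in seq_along(lv)) {
    for (b in seq_along(lv)) {
      if (b <= a) next
      xa <- r[g == lv[a]]
      xb <- r[g == lv[b]]
      z <- (mean(xa) - mean(xb)) /
        sqrt(s2 * (1 / length(xa) + 1 / length(xb)))
      res[[length(res) + 1L]] <- data.frame(
        group1 = lv[a], group2 = lv[b], z = z,
        p.value = 2 * pnorm(-abs(z))
      )
    }
  }
  do.call(rbind, res)
}

# small locus-table builder used across genome_map tests: family flags by
# rank position on one chromosome
loci_from_flags <- function(flags, chromosome = "chr1") {
  n <- length(flags)
  tibble::tibble(
    gene_id = sprintf("%s_g%02d", chromosome, seq_len(n)),
    chromosome = chromosome,
    start_bp = seq_len(n) * 10000L,
    end_bp = seq_len(n) * 10000L + 2000L,
    strand = "+",
    is_family_member = as.logical(flags),
    rank = seq_len(n)
  )
}
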