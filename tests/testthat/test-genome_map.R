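test_that("locus tables read from TSV with per-chromosome ranks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = c("g3", "g1", "g2"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(500L, 100L, 50L),
    end = c(600L, 200L, 90L),
    strand = c("+", "-", "+")
  ), f)
  loci <- read_loci(f, family_ids = c("g1", "g2"))
  expect_equal(loci$rank[loci$gene_id == "g1"], 1L)
  expect_equal(loci$rank[loci$gene_id == "g3"], 2L)
  expect_equal(loci$rank[loci$gene_id == "g2"], 1L)
  expect_equal(loci$is_family_member, c(TRUE, FALSE, TRUE)[match(loci$gene_id, c("g1", "g3", "g2"))])

  one <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "g", chromosome = "c",
                                  start = 1L, end = 2L, strand = "+"), one)
  expect_equal(read_loci(one)$rank, 1L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\tchromosome\tstart\tend\tstrand", empty)
  expect_equal(nrow(read_loci(empty)), 0L)
})

test_that("locus validation rejects bad coordinates and strands", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "bad", chromosome = "c",
                                  start = 10L, end = 5L, strand = "+"), f)
  expect_error(read_loci(f), "end < start")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "g", chromosome = "c",
                                  start = 1L, end = 5L, strand = "?"), f2)
  expect_error(read_loci(f2), "strand")
})

test_that("GFF3 gene features round-trip through read_loci", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\tgene\t500\t900\t.\t-\t.\tID=gB"
  ), f)
  loci <- read_loci(f, family_ids = "gB")
  expect_equal(nrow(loci), 2L)  # mRNA child ignored
  expect_equal(loci$start_bp[loci$gene_id == "gA"], 100L)
  expect_true(loci$is_family_member[loci$gene_id == "gB"])
})

test_that("chromosomal distribution reproduces the wheat percentages", {
  loci <- tibble::tibble(
    gene_id = paste0("g", 1:141),
    chromosome = rep(c("3A", "3B", "3D", "5B"), c(25, 33, 25, 58)),
    start_bp = seq_len(141) * 1000L,
    end_bp = seq_len(141) * 1000L + 500L,
    strand = "+",
    is_family_member = TRUE,
    rank = 1L
  )
  d <- gene_distribution(loci)
  expect_equal(sum(d$n), 141L)
  expect_equal(d$pct[d$chromosome == "3B"], 23.4)
  expect_equal(chrom_group_pct(loci, c("3A", "3B", "3D"))$pct, 58.8)
  expect_equal(chrom_group_pct(loci, c("3A", "3B", "3D"))$n, 83L)
  # truncation, not rounding: 83/141 = 58.865...
  expect_equal(chrom_group_pct(loci, c("3A", "3B", "3D"), truncate = FALSE)$pct,
               58.9)
  one <- dplyr::mutate(loci, chromosome = "3B")
  expect_equal(gene_distribution(one)$pct, 100.0)
})

test_that("distribution counts always sum to the family total", {
  set.seed(601)
  for (i in 1:20) {
    sim <- make_locus_table(n_chromosomes = sample(2:5, 1), seed = 600 + i)
    d <- gene_distribution(sim$loci)
    expect_equal(sum(d$n), sum(sim$loci$is_family_member))
  }
})

test_that("uniform expectation gives 14% for 3 of 21 chromosomes", {
  u <- uniform_expectation(3, 21)
  expect_equal(u$pct, 100 * 3 / 21)
  expect_equal(u$display, 14)
  expect_equal(uniform_expectation(21, 21)$pct, 100)
  expect_equal(uniform_expectation(0, 21)$pct, 0)
  expect_error(uniform_expectation(0, 0))
})

test_that("tandem clusters: forced cases", {
  # two adjacent family genes form one cluster of 2
  loci <- loci_from_flags(c(0, 0, 0, 0, 1, 1, 0, 0))
  cl <- detect_clusters(loci, max_intervening = 1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 2L)
  expect_equal(cl$intervening[[1]], 0L)
  # a single isolated family gene is no cluster
  expect_equal(nrow(detect_clusters(loci_from_flags(c(0, 1, 0)))), 0L)
  # span is the coordinate difference over the member range
  expect_equal(cl$span_bp, cl$end_bp - cl$start_bp)
})

test_that("planted clusters are recovered exactly", {
  sim <- make_locus_table(n_chromosomes = 2, genes_per_chromosome = 60,
                          cluster_spec = list(c(3L, 0L), c(2L, 1L), c(4L, 1L)),
                          seed = 611)
  cl <- detect_clusters(sim$loci, max_intervening = 1)
  expect_equal(sort(cl$size), c(2L, 3L, 4L))
  got <- lapply(cl$members, sort)
  truth_members <- split(sim$truth$gene_id[!is.na(sim$truth$cluster_id)],
                         sim$truth$cluster_id[!is.na(sim$truth$cluster_id)])
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(lapply(truth_members, sort), paste, "", collapse = ","))
})

test_that("cluster detection agrees with a brute-force maximal-run oracle", {
  set.seed(612)
  for (trial in seq_len(200)) {
    flags <- runif(sample(10:40, 1)) < 0.35
    k <- sample(0:2, 1)
    loci <- loci_from_flags(flags)
    mine <- detect_clusters(loci, max_intervening = k)
    oracle <- brute_force_clusters(loci, max_intervening = k)
    expect_equal(nrow(mine), length(oracle))
    if (nrow(mine) > 0) {
      expect_setequal(
        vapply(mine$members, paste, "", collapse = ","),
        vapply(oracle, function(o) paste(o$members, collapse = ","), "")
      )
    }
  }
})

test_that("clusters are invariant to coordinates while ranks are unchanged", {
  flags <- c(1, 1, 0, 1, 0, 0, 1, 1, 1)
  a <- loci_from_flags(flags)
  b <- a
  b$start_bp <- b$start_bp * 7L
  b$end_bp <- b$start_bp + 100L
  expect_equal(detect_clusters(a)$members, detect_clusters(b)$members)
})

test_that("region span reproduces the 1.26 Mb chromosome-3B region", {
  r <- region_span(32273198, 33537271)
  expect_equal(r$bp, 1264073)
  expect_equal(r$mb, 1.26)
  expect_equal(region_span(5, 5)$bp, 0)
  expect_equal(region_span(1, 1000001)$mb, 1.00)
  expect_error(region_span(10, 5), ">=")
})
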