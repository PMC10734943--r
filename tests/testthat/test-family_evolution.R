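test_that("ploidy normalization divides by 3/2/1/1 and rounds half up", {
  d <- normalize_ploidy(tibble::tibble(
    count = c(80L, 141L, 20L, 7L),
    ploidy = c("hexaploid", "hexaploid", "diploid", "haploid")
  ))
  expect_equal(d$per_haploid, c(80 / 3, 47, 20, 7))
  expect_equal(d$per_haploid_display, c(27, 47, 20, 7))
  expect_error(normalize_ploidy(tibble::tibble(count = 1, ploidy = "octoploid")),
               "unknown ploidy")
  expect_error(normalize_ploidy(tibble::tibble(count = -1, ploidy = "diploid")))
})

test_that("normalization neutralizes polyploidy", {
  set.seed(701)
  for (i in 1:50) {
    n <- sample(0:300, 1)
    pl <- sample(c("haploid", "diploid", "tetraploid", "hexaploid"), 1)
    scaled <- expected_polyploid_count(n, pl)
    back <- normalize_ploidy(tibble::tibble(count = scaled, ploidy = pl))
    expect_equal(back$per_haploid, n)
  }
  expect_equal(expected_polyploid_count(41, "hexaploid"), 123)
})

test_that("percent increase matches the wheat variety range", {
  p <- percent_increase(141, 238)
  expect_equal(p$display, 69)
  expect_equal(percent_increase(100, 150)$pct, 50)
})

test_that("Kruskal-Wallis H is 7.2 on the untied three-group example", {
  d <- tibble::tibble(value = as.numeric(1:9),
                      group = rep(c("g1", "g2", "g3"), each = 3))
  kw <- kruskal_wallis(d)
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2L)
  # two groups with symmetric ranks: H = 0
  sym <- tibble::tibble(value = c(1, 2, 3, 1, 2, 3),
                        group = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(sym)$statistic, 0)
  # degenerate: all observations identical
  flat <- tibble::tibble(value = rep(5, 6), group = rep(c("a", "b"), 3))
  expect_equal(kruskal_wallis(flat)$statistic, 0)
  expect_equal(kruskal_wallis(flat)$p.value, 1)
})

test_that("Kruskal-Wallis agrees with the reference implementation to 1e-9", {
  set.seed(702)
  for (trial in 1:50) {
    k <- sample(2:4, 1)
    x <- sample(0:30, sample(12:40, 1), replace = TRUE)  # heavy ties
    g <- sample(letters[1:k], length(x), replace = TRUE)
    while (length(unique(g)) < k) g <- sample(letters[1:k], length(x), TRUE)
    if (length(unique(x)) == 1) next
    ref <- stats::kruskal.test(x, factor(g))
    kw <- kruskal_wallis(tibble::tibble(value = x, group = g))
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p.value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("Dunn z and p agree with an independent computation to 1e-9", {
  set.seed(703)
  for (trial in 1:50) {
    k <- sample(2:4, 1)
    x <- sample(0:25, sample(12:40, 1), replace = TRUE)
    g <- sample(letters[1:k], length(x), replace = TRUE)
    while (length(unique(g)) < k) g <- sample(letters[1:k], length(x), TRUE)
    mine <- dunn_posthoc(tibble::tibble(value = x, group = g))
    ref <- dunn_oracle(x, g)
    expect_equal(mine$z, ref$z, tolerance = 1e-9)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$p.adjusted,
                 p.adjust(ref$p.value, method = "BH"), tolerance = 1e-9)
  }
})

test_that("Dunn handles degenerate inputs", {
  ident <- tibble::tibble(value = rep(3, 9),
                          group = rep(c("a", "b", "c"), each = 3))
  d <- dunn_posthoc(ident)
  expect_equal(d$z, rep(0, 3))
  expect_equal(d$p.adjusted, rep(1, 3))
  # single-member groups are allowed
  single <- tibble::tibble(value = c(1, 5, 9), group = c("a", "b", "c"))
  expect_equal(nrow(dunn_posthoc(single)), 3L)
})

test_that("BH adjustment never drops below the raw p-value", {
  set.seed(704)
  for (trial in 1:30) {
    x <- rnorm(30)
    g <- sample(letters[1:4], 30, replace = TRUE)
    while (length(unique(g)) < 4) g <- sample(letters[1:4], 30, TRUE)
    d <- dunn_posthoc(tibble::tibble(value = x, group = g))
    expect_true(all(d$p.adjusted >= d$p.value - 1e-12))
  }
})

test_that("parsimony reconstruction: forced and worked cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  # all leaves equal: every node equal, cost 0
  flat <- ancestral_counts(tr, c(A = 5, B = 5, C = 5))
  expect_equal(flat$cost, 0)
  expect_true(all(tidy(flat)$estimate == 5))
  # ((A:8, B:10), C:8): root 8, internal interval [8,10], cost 2
  fit <- ancestral_counts(tr, c(A = 8, B = 10, C = 8))
  expect_equal(fit$cost, 2)
  nodes <- tidy(fit)
  root <- nodes[nodes$type == "internal", ][1, ]
  inner <- nodes[nodes$type == "internal", ][2, ]
  expect_equal(root$estimate, 8)
  expect_equal(c(inner$lower, inner$upper), c(8L, 10L))
  expect_equal(inner$estimate, 8)
  expect_error(ancestral_counts(tr, c(A = 8, B = 10)), "without a count")
})

test_that("Sankoff cost equals the exhaustive minimum on small trees", {
  set.seed(705)
  for (trial in 1:25) {
    n <- sample(3:4, 1)
    tree <- ape::rtree(n)
    counts <- setNames(sample(0:20, n, replace = TRUE), tree$tip.label)
    fit <- ancestral_counts(tree, counts)
    expect_equal(fit$cost,
                 brute_force_parsimony(tree, counts, max(counts)))
  }
})

test_that("Sankoff cost equals an independent parsimony engine on larger trees", {
  set.seed(706)
  for (trial in 1:100) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    counts <- setNames(sample(0:20, n, replace = TRUE), tree$tip.label)
    fit <- ancestral_counts(tree, counts)
    states <- 0:max(counts)
    cost_mat <- outer(states, states, function(a, b) abs(a - b))
    dimnames(cost_mat) <- list(states, states)
    dat <- phangorn::phyDat(matrix(as.character(counts), ncol = 1,
                                   dimnames = list(names(counts), NULL)),
                            type = "USER", levels = as.character(states))
    ref <- phangorn::parsimony(tree, dat, method = "sankoff", cost = cost_mat)
    expect_equal(fit$cost, as.numeric(ref))
  }
})

test_that("point estimates form a minimal-cost assignment inside their intervals", {
  set.seed(707)
  for (trial in 1:40) {
    n <- sample(3:8, 1)
    tree <- ape::rtree(n)
    counts <- setNames(sample(0:15, n, replace = TRUE), tree$tip.label)
    fit <- ancestral_counts(tree, counts)
    nodes <- tidy(fit)
    expect_true(all(nodes$estimate >= nodes$lower &
                      nodes$estimate <= nodes$upper))
    assign <- nodes$estimate
    realized <- sum(abs(assign[fit$tree$edge[, 1]] -
                          assign[fit$tree$edge[, 2]]))
    expect_equal(realized, fit$cost)
  }
})

test_that("squared-cost option minimizes squared change", {
  set.seed(708)
  for (trial in 1:10) {
    tree <- ape::rtree(4)
    counts <- setNames(sample(0:8, 4, replace = TRUE), tree$tip.label)
    fit <- ancestral_counts(tree, counts, cost = "squared")
    expect_equal(fit$cost,
                 brute_force_parsimony(tree, counts, max(counts),
                                       cost = "squared"))
  }
})

test_that("reconstruction serializes to annotated newick", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  fit <- ancestral_counts(tr, c(A = 8, B = 10, C = 8))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_newick(fit, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), c("A", "B", "C"))
  expect_equal(as.integer(back$node.label),
               tidy(fit)$estimate[tidy(fit)$type == "internal"])
})
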