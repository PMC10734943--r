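PLOIDY_DIVISORS <- c(haploid = 1, diploid = 1, tetraploid = 2, hexaploid = 3)

#' Ploidy divisor for per-haploid-genome normalization
#'
#' Gene counts are divided by 3 in hexaploid species, by 2 in tetraploid
#' species and kept as-is for diploid and haploid species, neutralizing the
#' effect of whole-genome polyploidization.
#'
#' @param ploidy Character vector over
#'   `c("haploid", "diploid", "tetraploid", "hexaploid")`.
#' @return Numeric divisors.
#' @export
ploidy_divisor <- function(ploidy) {
  bad <- setdiff(unique(ploidy), names(PLOIDY_DIVISORS))
  if (length(bad)) stop("unknown ploidy class: ", paste(bad, collapse = ", "))
  unname(PLOIDY_DIVISORS[ploidy])
}

#' Normalize gene-family counts to copies per haploid genome
#'
#' @param data A data frame with columns `count` (integer >= 0) and
#'   `ploidy` (see [ploidy_divisor()]).
#' @return The input with two added columns: `per_haploid` (exact count /
#'   divisor) and `per_haploid_display` (integer, round half up): e.g. a
#'   hexaploid count of 80 gives 26.67, displayed as 27.
#' @export
#' @examples
#' normalize_ploidy(tibble::tibble(count = 80, ploidy = "hexaploid"))
normalize_ploidy <- function(data) {
  stopifnot(is.data.frame(data), all(c("count", "ploidy") %in% names(data)))
  if (any(data$count < 0)) stop("counts must be >= 0")
  div <- ploidy_divisor(data$ploidy)
  dplyr::mutate(tibble::as_tibble(data),
                per_haploid = .data$count / div,
                per_haploid_display = floor(.data$count / div + 0.5))
}

#' Expected polyploid count from a haploid-equivalent count
#'
#' Inverse of [normalize_ploidy()]: the family size expected if
#' polyploidization alone (no gain or loss) scaled an ancestral diploid
#' complement, e.g. a diploid ancestor with 41 genes predicts 123 in a
#' hexaploid derivative.
#'
#' @param count Haploid-equivalent count(s).
#' @param ploidy Target ploidy class(es).
#' @return Numeric expected count(s).
#' @export
expected_polyploid_count <- function(count, ploidy) {
  count * ploidy_divisor(ploidy)
}

#' Percent increase between two family sizes
#'
#' @param from,to Counts; `from > 0`.
#' @return A one-row tibble `pct` (exact) and `display` (round half up):
#'   e.g. 141 to 238 is an increase of almost 69%.
#' @export
percent_increase <- function(from, to) {
  stopifnot(from > 0)
  pct <- 100 * (to - from) / from
  tibble::tibble(pct = pct, display = floor(pct + 0.5))
}

rank_tie_term <- function(x) {
  t <- table(x)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Compares gene-family counts between k groups of species by the standard
#' rank-sum H statistic with tie correction; the p-value comes from the
#' chi-square approximation with k - 1 degrees of freedom. When every
#' observation is identical the statistic is defined as 0 with p = 1.
#'
#' @param data A data frame with one row per genome.
#' @param value,group Columns holding the (normalized) count and the group
#'   label; tidy-evaluated, defaults `value` and `group`.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
#' @examples
#' d <- tibble::tibble(value = 1:9, group = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis(d)  # H = 7.2
kruskal_wallis <- function(data, value = NULL, group = NULL) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  x <- if (rlang::quo_is_null(value)) data$value
       else rlang::eval_tidy(value, data)
  g <- if (rlang::quo_is_null(group)) data$group
       else rlang::eval_tidy(group, data)
  g <- factor(g)
  stopifnot(length(x) == length(g), nlevels(g) >= 2,
            all(table(g) >= 1))
  n <- length(x)
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  ni <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)
  correction <- 1 - rank_tie_term(x) / (n^3 - n)
  df <- nlevels(g) - 1L
  if (correction <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- h / correction
    p <- stats::pchisq(h, df, lower.tail = FALSE)
  }
  tibble::tibble(statistic = h, df = df, p.value = p,
                 method = "Kruskal-Wallis rank sum test (tie-corrected)")
}

#' Dunn's post-hoc test with Benjamini-Hochberg adjustment
#'
#' Pairwise follow-up to [kruskal_wallis()]: for each pair of groups the
#' Dunn z statistic is computed from pooled-rank means with tie correction,
#' two-sided p-values from the normal approximation, and the pairwise
#' family is adjusted by the Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust Adjustment method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return A tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p.value`, `p.adjusted`.
#' @export
dunn_posthoc <- function(data, value = NULL, group = NULL, p_adjust = "BH") {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  x <- if (rlang::quo_is_null(value)) data$value
       else rlang::eval_tidy(value, data)
  g <- if (rlang::quo_is_null(group)) data$group
       else rlang::eval_tidy(group, data)
  g <- factor(g)
  stopifnot(nlevels(g) >= 2)
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  sigma2 <- n * (n + 1) / 12 - rank_tie_term(x) / (12 * (n - 1))
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- match(pairs[1, k], levels(g))
    j <- match(pairs[2, k], levels(g))
    se2 <- sigma2 * (1 / ni[i] + 1 / ni[j])
    if (se2 <= 0) {
      z[k] <- 0
      p[k] <- 1
    } else {
      z[k] <- (rbar[i] - rbar[j]) / sqrt(se2)
      p[k] <- 2 * stats::pnorm(-abs(z[k]))
    }
  }
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                 p.value = p,
                 p.adjusted = stats::p.adjust(p, method = p_adjust))
}
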