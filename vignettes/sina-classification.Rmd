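---
title: "Classifying SINA E3 ubiquitin-ligases and tracing family expansion"
author: "sinascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying SINA E3 ubiquitin-ligases and tracing family expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinascan)
```

## The problem

Seven IN Absentia (SINA) proteins are monomeric RING-type E3
ubiquitin-ligases: a C-terminal SINA domain binds the substrate, an
N-terminal RING zinc-finger transfers ubiquitin. In plants the family has
expanded massively and unevenly — hexaploid bread wheat carries on the
order of 150–240 SINA genes, most of them concentrated at one end of the
homoeologous group-3 chromosomes, while *Arabidopsis thaliana* has about
20. The expansion left behind a large pool of rearranged, probably
pseudogenized copies next to a small, deeply conserved "ancestral" core.

`sinascan` implements the diagnostic machinery for telling those apart,
plus the comparative analytics used to describe the expansion:

1. a **degenerate consensus scanner** for the 58-residue ancestral SINA
   signature,
2. a **RING detector** that locates the domain through its eight
   metal-ligand residues,
3. the **four-class scheme** crossing \{ancestral vs modified SINA
   motif\} × \{RING present vs absent\},
4. **genome-map analytics**: chromosomal distribution, tandem-duplication
   clusters, region spans,
5. **family-evolution analytics**: ploidy normalization, Kruskal–Wallis /
   Dunn group comparison, and Sankoff parsimony reconstruction of
   ancestral family sizes,
6. seeded **synthetic-data generators** with known truth, so the whole
   pipeline is testable without any genome download.

Everything is tibble-in / tibble-out, so the steps chain with the pipe.

## The ancestral SINA motif and its grammar

The ancestral signature is written in a compact degenerate grammar:

```{r}
sina_consensus_pattern()
```

A unit is a residue letter or a two-letter alternative (`D/H`), an integer
repeats the preceding unit, and `X` is a wildcard matching any residue.
`parse_consensus()` expands this into explicit position classes:

```{r}
motif <- sina_ancestral_motif()
motif
```

Note the length: the printed pattern expands to **57** positions under the
grammar, although the signature is conventionally described as 58 aa. We
deliberately trust the grammar rather than hard-coding a length — the
pattern is configurable (`sina_config()`), so a corrected 58-position
pattern can be dropped in without code changes.

Scanning (`scan_degenerate()` / `scan_motif()`) slides the motif along the
sequence and reports every window violating at most `max_mismatches`
position classes. The default tolerance is **0**: the consensus already
encodes the observed variability through its 14 wildcard positions, and a
strict scan keeps the false-positive probability astronomically small — a
uniform-background window matches with probability
$0.05^{42} \times 0.10$ (42 fixed positions, one two-letter position), as
`match_probability()` reports. The tolerance is exposed for sensitivity
analyses; raising it can only add matches (a tested monotonicity
property).

Residues outside the 20-letter alphabet (ambiguity codes, `X`) are never
an error: they simply count as mismatches against any non-wildcard class.

## The RING detector

The canonical RING expression constrains the spacing of the metal-ligand
octet C-C-C-H-[C/H]-C-C-C:

```{r}
sina_ring_pattern()
```

`find_ring()` wraps the eight anchor tokens in capture groups and runs the
expression through a backtracking regex engine (PCRE), so the match
returns not just a window but the exact offsets of the eight ligands —
the residues whose loss (e.g. the first two cysteines) renders the domain
non-functional:

```{r}
find_ring("CAACAAAAAAAAACAAAHAACAACAAAACAAC")
```

`[C,H]` in the printed expression is interpreted as the residue class
\{C, H\}; a literal comma cannot occur in a protein sequence, so the comma
is presentational. By default only the leftmost match is returned;
`all = TRUE` enumerates every distinct feasible match window, which the
synthetic generator uses to prove a sequence contains no accidental RING.
Tests cross-check presence/absence against an independent regex engine
(TRE) on a thousand seeded sequences.

## The four-class scheme

Classification is a two-step decision per candidate protein: scan for the
ancestral motif, then for a RING domain.

```{r}
sina_classes()
```

"Modified" is the default for family candidates in which the ancestral
motif is not detected — the package does not re-verify SINA-family
membership, which upstream homology and domain-scanner screens establish;
this keeps the classifier self-contained and the class system exhaustive.
A protein with several motif hits is still simply "ancestral" (the hit
count is reported as evidence). Counting is per gene after
`select_isoforms()` by default, with a per-transcript audit mode
(`collapse_isoforms = FALSE`).

```{r}
sim <- make_proteome(c(ancestral_with_ring = 4, ancestral_without_ring = 1,
                       modified_with_ring = 3, modified_without_ring = 2),
                     seed = 11)
res <- sim$proteins |>
  qc_filter() |>
  select_isoforms() |>
  classify_genome(collapse_isoforms = TRUE, species_tag = "synthetic")
res$summary
```

### QC and isoform selection

The screening rules mirror practice for large proteome surveys: sequences
must start with methionine and contain no unknown residue (`X`); a
trailing `*` stop mark is stripped first. Rejection reasons are reported
with a fixed priority (`empty_sequence > non_met_start > unknown_residue`)
so reports are deterministic. Per gene, the isoform with the most detected
domains is retained. The original rule counts external domain-scanner
hits; since those scanners are out of scope here, the default scorer
counts the two in-scope domains (ancestral motif, RING) and is pluggable
(`scorer =`). Ties go to the lexicographically smallest isoform label — a
package decision, made so that selection is order-invariant.

## Genome-map analytics

`read_loci()` ingests GFF3 gene features (children ignored) or a
five-column TSV and assigns each gene its rank along its chromosome.
Three conventions matter and are deliberate:

* **Percentages are truncated**, not rounded, to one decimal:
  83/141 = 58.865…% is reported as 58.8%, matching the convention of the
  source tables. `truncate = FALSE` switches to rounding.
* **Region span is `end − start`** (not `+1`): 32273198..33537271 spans
  1264073 bp = 1.26 Mb. The 1 bp difference is immaterial at Mb scale.
* **Tandem-cluster adjacency is by gene rank**, not physical distance:
  clusters are maximal runs of ≥ 2 family genes in which consecutive
  members are separated by at most `max_intervening` (default 1)
  non-family genes. This makes detection invariant to intergenic distances
  and matches the qualitative description of "contiguous or tandem genes,
  sometimes separated by one or a few other genes".

```{r}
loci <- make_locus_table(cluster_spec = list(c(3L, 0L), c(2L, 1L)),
                         seed = 5)$loci
detect_clusters(loci, max_intervening = 1)[, c("chromosome", "size", "span_bp")]
uniform_expectation(3, 21)
```

## Family-evolution analytics

### Ploidy normalization

Counts are divided by 3 (hexaploid), 2 (tetraploid) or 1
(diploid/haploid); the exact rational value is kept and a round-half-up
display integer is added (80 hexaploid → 26.67 → "27").

### Group comparison

`kruskal_wallis()` implements the tie-corrected rank-sum H with the
chi-square approximation; `dunn_posthoc()` the pairwise Dunn z from pooled
ranks with the same tie term, two-sided normal p-values and
Benjamini–Hochberg step-up adjustment. Degenerate inputs are defined, not
errors: all-identical observations give H = 0, p = 1; a zero pooled
variance gives z = 0, p = 1; single-member groups are allowed. Both are
validated to 1e-9 against independent implementations in the test suite.

### Ancestral family sizes by parsimony

`ancestral_counts()` reconstructs integer gene counts at internal nodes of
a user-supplied rooted species tree by a Sankoff dynamic program over
states `0..max(leaf count)` with linear per-edge cost `|child − parent|` —
the standard count-parsimony choice; squared cost is available
(`cost = "squared"`). The reconstruction method in the source analysis was
a general parsimony tool whose cost variant is unstated; linear-cost
Sankoff is the natural reading for integer counts, and both variants are
exposed so neither is hidden.

Each node reports its **optimal interval** (the argmin of its bottom-up
cost vector; at the root this is the set of globally optimal states) plus
a **point estimate**: the root takes the floor of its interval midpoint,
and each descendant clamps its parent's estimate into its own interval —
for the linear cost this choice is conditionally optimal, so the point
assignment attains the minimal total cost (a tested property). For the
squared cost the clamp rule is kept for consistency but only the interval
and the cost carry the optimality guarantee. Reporting the full interval
means the tie-break hides no information.

```{r}
tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
fit <- ancestral_counts(tr, c(A = 8, B = 10, C = 8))
tidy(fit)
glance(fit)
```

Trees are always user-supplied newick: the published species-tree figure
is not machine-readable, so the package does not guess a topology. Both
raw and normalized counts can be used at the leaves; whether the original
figure used one or the other is unstated, so both modes are the user's
choice.

## The synthetic world

The generators exist so that every detector can be validated against a
known truth without downloading genomes:

* `make_protein()` / `make_proteome()` sample background residues
  (uniform over the 20 amino acids by default — the stated null for the
  false-positive calibration; a frequency table can be supplied), fix the
  first residue to methionine so records pass QC, and plant a concrete
  motif realization (wildcards sampled, fixed positions exact) and/or a
  minimal-width RING segment. The draw is rejected and resampled until
  the only detector hits are the planted ones, capped at 1000 attempts;
  an accidental RING on uniform background has probability of order
  1e-4 per sequence, so the cap is never approached in practice. Record
  lengths default to 250–420 aa, bracketing the ~334 aa average reported
  for wheat SINA proteins.
* `make_locus_table()` plants tandem clusters separated by gaps strictly
  beyond the detection threshold.
* `make_count_tree()` evolves an integer count root-to-leaves with a
  per-edge change probability and ± uniform steps (clipped at 0),
  recording the realized total change, which upper-bounds the
  reconstruction cost.

All generators are pure functions of (parameters, seed). What a green test
on this world establishes: the detectors find exactly what is planted and
nothing else on i.i.d. background, and the analytics are exact on their
combinatorial definitions. What it does not establish: performance on real
proteomes, where family membership, alternative splicing and compositional
bias are screened by upstream tools (homology search, domain scanners)
that are intentionally out of scope, and where published per-genome counts
depend on pinned genome versions.

## Numerical and degenerate-input choices

* Coordinates in all user-facing tables are 1-based inclusive (R and
  Bioconductor convention).
* Scanning is case-insensitive; sequences are uppercased on ingest.
* An empty proteome yields an all-zero summary; an empty sequence is a
  classification error.
* `aggregate_summaries()` of an empty list is the zero row.
* Match-probability frequencies must sum to 1 within 1e-9.
* Seeds are required arguments for every generator; derived sub-seeds
  stay below 2^31.

## Limitations

* The classifier presumes its input is a SINA-family candidate set;
  feeding it an arbitrary proteome labels every non-SINA protein
  "modified" rather than rejecting it.
* The strict 0-mismatch default means single substitutions at fixed
  consensus positions are reported as "modified"; raise `max_mismatches`
  to probe that boundary.
* Cluster detection is within-chromosome only; synteny between species is
  out of scope.
* Parsimony reconstruction gives no uncertainty beyond the optimal
  interval; likelihood gain/loss models are out of scope.
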