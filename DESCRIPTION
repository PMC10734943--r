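Package: sinascan
Title: Identification and Classification of SINA E3 Ubiquitin-Ligase Proteins in Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and classify Seven IN Absentia (SINA) family
    E3 ubiquitin-ligase proteins in plant proteomes. Implements a two-factor
    classification based on a degenerate 58-residue ancestral SINA consensus
    motif and a canonical RING zinc-finger domain located through its eight
    metal-ligand residues, together with gene-family expansion analytics:
    chromosomal distribution and tandem-duplication cluster detection,
    ploidy-normalized copy-number comparison across species groups
    (Kruskal-Wallis with Dunn post-hoc tests), and Sankoff parsimony
    reconstruction of ancestral gene-family sizes on a species tree.
    Includes seeded synthetic-data generators with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
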