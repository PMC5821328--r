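Package: virowinnow
Title: Virus Discovery by Metagenomic Winnowing in Insect RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale implementation of the successive-winnowing
    strategy used to prospect for novel RNA viruses in pooled insect
    (fire ant) RNA sequencing libraries: median-quality read filtering,
    k-mer host subtraction, six-frame translated homology search with
    Karlin-Altschul E-values and taxonomic binning, greedy
    overlap-layout-consensus assembly of virus-binned reads with
    per-library singleton accounting, known-virus matching and exclusion
    rules, cross-library expression prioritization of viral prospects,
    dicistrovirus genome annotation (ORFs, architecture, conserved
    domains, polyadenylation, replicative-strand accounting), and
    neighbor-joining RdRp phylogenies with bootstrap support. Includes a
    seeded synthetic metavirome generator with a ground-truth manifest,
    fixtures transcribing the published fire-ant survey tables, and a
    command-line driver for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
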