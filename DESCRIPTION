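Package: hexdel
Title: Deletion Calling and Meiotic Analysis for Irradiated Hexaploid Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gamma-ray-induced chromosomal deletions from SNP-array
    signal intensities in allohexaploid genomes. Normalizes per-marker log-R
    intensities against a wild-type reference, locates mean shifts with binary
    segmentation, and confirms candidate intervals with off-target-variant
    (OTV) density, weak-signal masks and studentized-residual outlier tests.
    Intersects called deletions with gene annotations and orthogroup tables to
    count homoeologous groups lost on one, two or all three subgenomes.
    Summarizes meiotic metaphase-I pairing configurations (univalents,
    bivalents, multivalents) into chiasma counts, and dispatches two-group
    comparisons through a Shapiro-Wilk normality gate to a t-test or
    Kruskal-Wallis test. Annotates CDS SNPs to codon and amino-acid
    consequences. A synthetic-data module generates every input the pipeline
    consumes, with ground-truth records for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
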