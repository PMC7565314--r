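Package: nano16S
Title: Nanopore Versus Illumina 16S rRNA Gene Profiling: Per-Read
    Classification, Platform Concordance and Primer Dropout Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements the post-classification stage of a nanopore 16S
    rRNA amplicon workflow: lowest-common-ancestor style summarisation of the
    top three BLAST hits per read (num_genus_taxid), coverage and quality
    based read exclusion for the Albacore and Guppy basecaller eras, genus
    abundance profiles with the usual alpha-diversity summaries (observed
    genera, inverse Simpson, Shannon, rarefaction), paired-platform
    concordance statistics (sum of agreement, Bland-Altman limits,
    prevalence chi-square, paired t, Pearson/UPGMA clustering, Bray-Curtis
    PERMANOVA), a degenerate-primer annealing screen that predicts per-taxon
    amplification dropout, and a seeded two-platform synthetic data
    generator reproducing the two failure mechanisms seen in nasal
    microbiota data: reference-database sparsity forcing family-level
    fallback, and primer mismatch causing genus dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    vegan,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
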