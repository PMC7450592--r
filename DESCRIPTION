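Package: svgeno
Title: Five-Class Genotyping of Structural Variants Co-Occurring with Copy-Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes candidate structural variants (SV) in tumor-like
    sequencing data into five classes that jointly account for zygosity and a
    co-occurring copy-number variant (CNV): normal homozygote, homozygous
    variant, heterozygous variant, and heterozygous variant with the CNV on
    the mutated or on the wild haplotype. Fifteen alignment-derived features
    (insert-size concordance, CIGAR-based mapping categories, read direction,
    mapping-quality-weighted read depth, variant length) are extracted per
    candidate call from SAM/BAM plus VCF, and classified with a multiclass
    relevance vector machine: a sparse Bayesian kernel classifier with a
    multinomial-probit likelihood that emits a probability for each of the
    five genotypes. Includes a diploid genome and paired-end read simulator
    with planted SVs, tandem-duplication CNVs and SNVs for end-to-end
    evaluation, a copy-number-by-coverage accuracy grid, kernel-parameter
    sweeps, relevance-vector sparsity traces, and equal-probability invalid-
    sample accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rsamtools,
    vcfR,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
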