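# svgeno

Five-class genotyping of structural variants that co-occur with copy-number
variants, for tumor-like short-read sequencing data.

## The problem

A heterozygous structural variant (SV) normally leaves a 1:1 ratio of
variant-supporting to reference-supporting read pairs. When a copy-number
variant (CNV) of copy number *n* amplifies the haplotype carrying the SV,
that ratio moves towards *n*:1; when it amplifies the wild haplotype, towards
1:*n*. Genotypers that only distinguish hom/het/absent systematically
misread such loci. svgeno classifies each candidate SV call (from a VCF,
against coordinate-sorted SAM/BAM alignments) into five genotypes:

* `N`  — no variant (false candidate)
* `G1` — homozygous variant
* `G2` — heterozygous variant, no CNV
* `G3` — heterozygous variant, CNV on the mutated haplotype
* `G4` — heterozygous variant, CNV on the wild haplotype

and reports a full probability vector [p_N, p_G1, p_G2, p_G3, p_G4],
Σp = 1, per call.

## Method

Fifteen features are extracted per call over the *mutated region*
[POS−100, END+100] (membership by a record's POS, closed intervals):
insert-size concordant/discordant pair counts against μ ± 3σ, CIGAR-based
categories (fully/single/incompletely/split-mapped, unmapped), exact-FLAG
direction counts (83/163), summed MAPQ, read depth D = n/L,
MAPQ-weighted depth W_RD = Σ(Q_i/Q_max)/L, its extended-region variant,
reads in the variation vicinity [POS−⌊L/10⌋, END+⌊L/10⌋], and the variant
length L.

The classifier is a **multiclass relevance vector machine**: a sparse
Bayesian kernel classifier with a multinomial-probit likelihood
(auxiliary targets y_c = k(x)ᵀw_c + ε, label = argmax_c y_c). Training
alternates exact truncated-Gaussian expectations of the auxiliary
variables (Gauss–Hermite quadrature), a ridge-style weight posterior under
per-sample scale hyperparameters shared across classes, and MacKay type-II
maximum-likelihood scale updates that prune samples whose scale diverges.
The surviving samples are the relevance vectors; their count per iteration
is recorded and can be plotted. An RBF kernel on z-scored features is used,
width selected by the package's cross-validated sweep (`kernel_sweep()`).

A full simulator (`simulate_sv_data()`) plants the five genotype classes —
CNVs as haplotype-specific tandem duplications — on a diploid genome,
samples paired-end reads, and emulates the alignment signals (CIGAR, FLAG,
MAPQ, TLEN) through exact coordinate maps, so the entire pipeline is
testable end to end with no external data.

## Worked example

```r
library(svgeno)

cfg <- sim_config(seed = 1)                # 1 Mbp, 300 calls, coverage 10x
train <- simulate_training_set(cfg)        # simulate + extract features
fit <- mrvm(train$features, train$labels)  # multiclass RVM
fit
#> Multiclass relevance vector machine
#>   classes: N, G1, G2, G3, G4
#>   kernel: gaussian_rbf (parameter 5), features z-scored
#>   relevance vectors: 6 of 300 training samples
#>   iterations: 447 (converged)

cfg2 <- cfg; cfg2$seed <- 2                # independent test replicate
test <- simulate_training_set(cfg2)
calls <- predict(fit, test$features, type = "call")
evaluate_genotypes(calls, test$truth)
#> samples: 300  invalid (tie): 0
#> overall accuracy: 0.8733  valid-sample accuracy: 0.8733
#>       N G1 G2 G3 G4
#>   N  59  0  0  0  1
#>   G1  0 69  3  8  0
#>   G2  0  5 74  1  0
#>   G3  0  6  4 36  4
#>   G4  0  1  0  5 24

head(calls, 3)
#>   call_id      p_N     p_G1   p_G2     p_G3     p_G4 label
#> 1   sv001 3.74e-06 3.41e-08 0.0115 4.29e-01 0.559157    G4
#> 2   sv002 2.44e-03 8.67e-03 0.9868 4.09e-04 0.001647    G2
#> 3   sv003 9.46e-01 1.35e-24 0.0536 3.19e-10 0.000116     N
```

The model fits in seconds: only 6 of 300 training samples survive as
relevance vectors, and 262 of 300 independent test calls are genotyped
correctly (87.3%), with the residual confusion concentrated where it should
be — between G1/G3 (both variant-rich) and G3/G4 (CNV placement).

Genotyping real data uses the same functions with files:

```r
fit <- read_mrvm("model.rds")
calls <- genotype_sv("candidates.vcf", "sample.bam", fit,
                     vcf_out = "candidates.genotyped.vcf")
```

A thin command-line wrapper with `simulate`, `extract`, `train`, `sweep`,
`genotype`, `evaluate` and `grid` subcommands is installed at
`inst/cli/svgeno.R`.

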