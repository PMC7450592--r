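#' @keywords internal
"_PACKAGE"

## Fixed genotype class order used everywhere (labels, probability columns,
## confusion matrices, deterministic tie-breaking).
GENOTYPE_CLASSES <- c("N", "G1", "G2", "G3", "G4")

#' Genotype class labels
#'
#' The five genotype classes, in the fixed order used for probability
#' columns, confusion matrices and deterministic tie-breaking:
#' `N` (no variant), `G1` (homozygous variant), `G2` (heterozygous variant,
#' no CNV), `G3` (heterozygous variant with a CNV on the mutated haplotype),
#' `G4` (heterozygous variant with a CNV on the wild haplotype).
#'
#' @return Character vector of length 5.
#' @export
genotype_classes <- function() GENOTYPE_CLASSES

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards. Keeps simulation entry points
## deterministic without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and integer context values, staying
## within the 32-bit signed range. Used by grid experiments so every cell and
## repeat gets a distinct, reproducible stream.
derive_seed <- function(base_seed, ...) {
  parts <- c(base_seed, unlist(list(...)))
  s <- 0
  for (p in parts) s <- (s * 1103515245 + as.numeric(p) * 12345 + 12345) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
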