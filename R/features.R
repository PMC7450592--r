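## The fifteen per-call features.
##
## All region membership is by the record's POS (leftmost mapped base; for
## unmapped records the anchoring mate position) falling in the closed
## interval. Counts are raw; any scaling for the classifier happens at
## training time, not here.

FEATURE_NAMES <- c("abnormal_read", "normal_read", "incompletely_mapped",
                   "fully_mapped", "split_mapped", "single_mapped",
                   "unmapped", "mapq_sum", "read_depth",
                   "weighted_read_depth", "ext_weighted_read_depth",
                   "affected_reads", "variant_length",
                   "direction1", "direction2")

#' Feature column names in canonical order
#' @return Character vector of the 15 feature names (F1--F15).
#' @export
feature_names <- function() FEATURE_NAMES

#' Count insert-size concordant and discordant pairs
#'
#' Over the region's read pairs, a pair is *normal* when its absolute
#' observed template length lies in `[mu - 3 sigma, mu + 3 sigma]`
#' (inclusive) and *abnormal* otherwise. Pairs with an absent or unmapped
#' mate are counted in neither.
#'
#' @param pairs pair rows from [collect_region_records()].
#' @param stats insert statistics ([insert_stats()] or
#'   [estimate_insert_stats()]).
#' @return Named vector `c(normal_read, abnormal_read)`.
#' @export
count_insert_size_features <- function(pairs, stats) {
  ok <- pairs$mapped1 & pairs$mapped2 & !is.na(pairs$insert_size)
  ins <- pairs$insert_size[ok]
  lo <- stats$mu - 3 * stats$sigma
  hi <- stats$mu + 3 * stats$sigma
  normal <- sum(ins >= lo & ins <= hi)
  c(normal_read = normal, abnormal_read = length(ins) - normal)
}

#' Count the CIGAR/mapping-category features
#'
#' Using the full-length match token `"<read_length>M"`:
#' \itemize{
#'   \item `fully_mapped`: pairs whose two mates both carry the full token;
#'   \item `single_mapped`: in-region mapped records carrying the token
#'     whose mate does not qualify (absent, unmapped, or non-full-match);
#'   \item `incompletely_mapped`: in-region mapped records whose CIGAR
#'     differs from the token (clips/indels);
#'   \item `split_mapped`: pairs with exactly one mate's POS inside the
#'     region and the other outside (both mapped);
#'   \item `unmapped`: unmapped-flag records anchored (by mate position) in
#'     the region.
#' }
#'
#' @param records in-region records from [collect_region_records()].
#' @param pairs pair rows (with `in1`/`in2` indicators) from the same call.
#' @param read_length read length defining the full-match CIGAR token.
#' @return Named integer vector of the five counts.
#' @export
count_alignment_features <- function(records, pairs, read_length = 100) {
  token <- paste0(read_length, "M")
  full_pair <- pairs$mapped1 & pairs$mapped2 &
    !is.na(pairs$cigar1) & !is.na(pairs$cigar2) &
    pairs$cigar1 == token & pairs$cigar2 == token
  split_pair <- pairs$mapped1 & pairs$mapped2 & xor(pairs$in1, pairs$in2)

  mapped <- !records$unmapped
  incomplete <- mapped & records$cigar != token
  ## single-mapped needs the mate's CIGAR: look it up in the pair rows
  m <- match(records$qname, pairs$qname)
  first <- bitwAnd(records$flag, 128L) == 0L
  mate_cigar <- ifelse(first, pairs$cigar2[m], pairs$cigar1[m])
  mate_mapped <- ifelse(first, pairs$mapped2[m], pairs$mapped1[m])
  ## a pair row with an all-NA second slot is a mate-never-observed QNAME
  ## (stored in slot 1 whichever mate it is): its mate never qualifies
  mate_ok <- !is.na(m) & !is.na(pairs$flag2[m]) &
    !is.na(mate_mapped) & mate_mapped &
    !is.na(mate_cigar) & mate_cigar == token
  single <- mapped & records$cigar == token & !mate_ok

  c(fully_mapped = sum(full_pair),
    single_mapped = sum(single),
    incompletely_mapped = sum(incomplete),
    split_mapped = sum(split_pair),
    unmapped = sum(records$unmapped))
}

#' Count direction features
#'
#' Records whose FLAG equals exactly 83 (direction 1) or exactly 163
#' (direction 2); exact integer equality, so compound flags (e.g. secondary
#' alignments) do not count.
#'
#' @param records in-region records.
#' @return Named vector `c(direction1, direction2)`.
#' @export
count_direction_features <- function(records) {
  c(direction1 = sum(records$flag == 83L),
    direction2 = sum(records$flag == 163L))
}

#' Sum mapping qualities over the region's records
#' @param records in-region records.
#' @return Integer sum of MAPQ (unmapped records contribute their stored
#'   MAPQ, normally 0).
#' @export
sum_mapping_qualities <- function(records) sum(records$mapq)

#' Read depth of the mutated region
#'
#' `D = n / L` with `n` the number of in-region mapped records and `L` the
#' variant length. For `L = 0` (insertion points) the core-region width is
#' substituted as denominator.
#'
#' @param records in-region records.
#' @param L variant length (bp).
#' @param fallback_width denominator used when `L = 0`.
#' @return Numeric depth.
#' @export
read_depth <- function(records, L, fallback_width = NULL) {
  n <- sum(!records$unmapped)
  den <- if (L > 0) L else fallback_width
  if (is.null(den) || den <= 0) stop("read_depth: L = 0 and no fallback width")
  n / den
}

#' Mapping-quality-weighted read depth
#'
#' Each in-region mapped record contributes weight `w_i = Q_i / Q_max`
#' (its MAPQ over the file-wide maximum MAPQ); the feature is
#' `W_RD = sum(w_i) / L`. Since every `w_i <= 1`, `W_RD <= D`.
#'
#' @param records in-region (or extended-region) records.
#' @param L variant length (bp); shared denominator with [read_depth()].
#' @param q_max file-wide maximum MAPQ; if 0 the feature is defined as 0.
#' @param fallback_width denominator when `L = 0`.
#' @return Numeric weighted depth.
#' @export
weighted_read_depth <- function(records, L, q_max, fallback_width = NULL) {
  if (q_max <= 0) return(0)
  den <- if (L > 0) L else fallback_width
  if (is.null(den) || den <= 0) stop("weighted_read_depth: L = 0 and no fallback width")
  sum(records$mapq[!records$unmapped] / q_max) / den
}

#' Count reads starting in the variation vicinity
#'
#' Records whose POS lies in `[pos - floor(L/10), end + floor(L/10)]`
#' (inclusive).
#'
#' @param alignments full alignment frame.
#' @param vic_start,vic_end vicinity bounds from [derive_regions()].
#' @return Integer count.
#' @export
count_affected_reads <- function(alignments, vic_start, vic_end) {
  sum(!is.na(alignments$pos) & alignments$pos >= vic_start &
        alignments$pos <= vic_end)
}

#' Extract the 15-feature matrix for a set of candidate calls
#'
#' Runs all feature counters over each call's core, extended and vicinity
#' regions. `Q_max` is the file-wide maximum MAPQ (computed once); insert
#' statistics are estimated from the file when not supplied.
#'
#' @param calls an [sv_calls()] data frame.
#' @param alignments alignment frame from [read_alignments()] (or a path to
#'   a SAM/BAM file).
#' @param stats optional [insert_stats()]; estimated when `NULL`.
#' @param read_length read length in bp.
#' @param reference_length contig length for region clamping.
#' @return A data frame of class `sv_features`: `call_id` plus the 15
#'   feature columns in canonical order ([feature_names()]).
#' @export
extract_features <- function(calls, alignments, stats = NULL,
                             read_length = 100, reference_length = Inf) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  pair_table <- build_pair_table(alignments)
  if (is.null(stats)) stats <- estimate_insert_stats(pair_table)
  q_max <- max(alignments$mapq, 0)
  reg <- derive_regions(calls, read_length, reference_length)
  n <- nrow(calls)
  ## sorted-position indexes: closed-interval membership by binary search
  ## (identical semantics to a full scan over POS; NA POS is never in-region)
  idx_of <- function(values) {
    keep <- which(!is.na(values))
    o <- keep[order(values[keep])]
    v <- values[o]
    function(s, e) {
      lo <- findInterval(s - 1, v) + 1L
      hi <- findInterval(e, v)
      if (hi < lo) integer(0) else o[lo:hi]
    }
  }
  rec_idx <- idx_of(alignments$pos)
  p1_idx <- idx_of(pair_table$pos1)
  p2_idx <- idx_of(pair_table$pos2)
  out <- matrix(0, nrow = n, ncol = length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    cs <- reg$core_start[i]; ce <- reg$core_end[i]
    records <- alignments[rec_idx(cs, ce), , drop = FALSE]
    pi <- sort(unique(c(p1_idx(cs, ce), p2_idx(cs, ce))))
    pairs <- pair_table[pi, , drop = FALSE]
    pairs$in1 <- !is.na(pairs$pos1) & pairs$pos1 >= cs & pairs$pos1 <= ce
    pairs$in2 <- !is.na(pairs$pos2) & pairs$pos2 >= cs & pairs$pos2 <= ce
    ext <- alignments[rec_idx(reg$ext_start[i], reg$ext_end[i]), , drop = FALSE]
    L <- calls$length[i]
    fw <- ce - cs + 1
    ins <- count_insert_size_features(pairs, stats)
    alnf <- count_alignment_features(records, pairs, read_length)
    dirs <- count_direction_features(records)
    out[i, ] <- c(ins["abnormal_read"], ins["normal_read"],
                  alnf["incompletely_mapped"], alnf["fully_mapped"],
                  alnf["split_mapped"], alnf["single_mapped"],
                  alnf["unmapped"],
                  sum_mapping_qualities(records),
                  read_depth(records, L, fw),
                  weighted_read_depth(records, L, q_max, fw),
                  weighted_read_depth(ext, L, q_max, fw),
                  length(rec_idx(reg$vic_start[i], reg$vic_end[i])),
                  L, dirs["direction1"], dirs["direction2"])
  }
  res <- data.frame(call_id = calls$id, out, stringsAsFactors = FALSE)
  attr(res, "q_max") <- q_max
  attr(res, "insert_stats") <- stats
  class(res) <- c("sv_features", "data.frame")
  res
}

#' Write / read a feature matrix as headered TSV
#' @param features an `sv_features` frame.
#' @param path file path.
#' @return `path` (write) or the features frame (read).
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("call_id", FEATURE_NAMES)
  if (!all(need %in% names(d)))
    stop("read_features: missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  class(d) <- c("sv_features", "data.frame")
  d[, need]
}
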