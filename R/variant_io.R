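## Candidate-call I/O, region arithmetic and insert-size statistics.
##
## Coordinates are 1-based, fully closed intervals throughout, matching SAM
## POS semantics: a record belongs to a region iff its leftmost mapped base
## lies in [start, stop] inclusive.

#' Construct a set of candidate SV calls
#'
#' @param id character vector of call identifiers (unique).
#' @param chrom chromosome/contig name.
#' @param pos 1-based start position (bp).
#' @param end 1-based end position (bp); must satisfy `end >= pos`.
#' @param sv_type one of `"INS"`, `"DEL"`, `"INV"`, `"CPX"`, `"NONE"`.
#'
#' @return A `data.frame` of class `sv_calls` with columns
#'   `id, chrom, pos, end, sv_type, length`, where `length = abs(pos - end)`.
#' @export
sv_calls <- function(id, chrom, pos, end, sv_type = "NONE") {
  pos <- as.integer(pos); end <- as.integer(end)
  if (any(is.na(pos)) || any(is.na(end)))
    stop("sv_calls: pos/end must be integral and non-missing")
  bad <- which(end < pos)
  if (length(bad))
    stop("sv_calls: END < POS for call(s): ", paste(id[bad], collapse = ", "))
  sv_type <- as.character(sv_type)
  ok <- sv_type %in% c("INS", "DEL", "INV", "CPX", "NONE")
  if (!all(ok))
    stop("sv_calls: unknown sv_type: ", paste(unique(sv_type[!ok]), collapse = ", "))
  if (anyDuplicated(id)) stop("sv_calls: duplicated call ids")
  out <- data.frame(id = as.character(id), chrom = as.character(chrom),
                    pos = pos, end = end, sv_type = sv_type,
                    length = abs(pos - end), stringsAsFactors = FALSE)
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Read candidate SV calls from a VCF file
#'
#' Each record becomes one call. The end coordinate is taken from the INFO
#' `END` key; when absent, it falls back to `POS + |SVLEN|` if `SVLEN` is
#' present. Records with no resolvable end are rejected. (VCF 4.x carries END
#' in the INFO column; an explicit eighth "End" column only exists in the
#' simplified tab dialect read by [read_sv_table()].)
#'
#' @param path path to an (uncompressed or bgzipped) VCF 4.x file.
#' @return An [sv_calls()] data frame, with a `gtclass` column appended when
#'   the file carries the `GTCLASS` INFO key (simulator truth sets).
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) stop("read_sv_vcf: no such file: ", path)
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(sv_calls(character(), character(), integer(), integer(), character()))
  }
  pos <- as.integer(fix[, "POS"])
  endv <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "END")))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "SVLEN")))
  noend <- is.na(endv)
  endv[noend] <- pos[noend] + abs(svlen[noend])
  if (any(is.na(endv)))
    stop("read_sv_vcf: record(s) without resolvable END (no INFO END or SVLEN): rows ",
         paste(which(is.na(endv)), collapse = ", "))
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  svtype[is.na(svtype)] <- "NONE"
  id <- fix[, "ID"]
  miss <- is.na(id) | id == "."
  id[miss] <- paste0("call", seq_len(nrow(fix)))[miss]
  calls <- sv_calls(id, fix[, "CHROM"], pos, endv, svtype)
  gt <- vcfR::extract.info(vcf, "GTCLASS")
  if (!all(is.na(gt))) calls$gtclass <- gt
  calls
}

## Light structural validation so malformed lines are reported with their
## line number before vcfR parses the file.
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("read_sv_vcf: malformed VCF line ", i, ": expected >= 8 fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop("read_sv_vcf: malformed VCF line ", i, ": non-integer POS '", f[2], "'")
  }
  invisible(TRUE)
}

#' Write candidate SV calls to a VCF 4.2 file
#'
#' INFO carries `END`, `SVTYPE`, `SVLEN` and, when a `gtclass` column is
#' present, the custom key `GTCLASS`. Extra numeric columns named in
#' `info_extra` are appended as additional INFO keys.
#'
#' @param calls an [sv_calls()] data frame.
#' @param path output path.
#' @param contig_length length of the contig, written to the `##contig` line.
#' @param info_extra named list of per-call vectors to append as INFO keys.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, contig_length = NULL, info_extra = NULL) {
  chrom <- unique(calls$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_length) && length(chrom) == 1)
      sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(contig_length)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=GTCLASS,Number=1,Type=String,Description=\"Five-class genotype: N,G1,G2,G3,G4\">",
    if (!is.null(info_extra))
      sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
              names(info_extra), names(info_extra)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  alt <- ifelse(calls$sv_type == "NONE", ".", paste0("<", calls$sv_type, ">"))
  info <- sprintf("END=%d;SVTYPE=%s;SVLEN=%d", calls$end, calls$sv_type, calls$length)
  if (!is.null(calls$gtclass)) info <- paste0(info, ";GTCLASS=", calls$gtclass)
  if (!is.null(info_extra))
    for (k in names(info_extra))
      info <- paste0(info, ";", k, "=", format(info_extra[[k]], trim = TRUE))
  rows <- sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s",
                  calls$chrom, calls$pos, calls$id, alt, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read candidate calls from the simplified tab dialect
#'
#' A headered TSV with columns `id, chrom, pos, end, sv_type`. Non-standard;
#' used by test fixtures only.
#'
#' @param path path to the TSV file.
#' @return An [sv_calls()] data frame.
#' @export
read_sv_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "end", "sv_type")
  if (!all(need %in% names(d)))
    stop("read_sv_table: missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  sv_calls(d$id, d$chrom, d$pos, d$end, d$sv_type)
}

#' Derive the three feature-counting regions for each call
#'
#' For a call with coordinates `[pos, end]`, variant length `L` and read
#' length `r` (default 100 bp):
#' \itemize{
#'   \item core (mutated region): `[pos - r, end + r]`
#'   \item extended region: `[pos - 2r, end + 2r]`
#'   \item variation vicinity: `[pos - floor(L/10), end + floor(L/10)]`
#' }
#' All bounds are clamped to `[1, reference_length]`.
#'
#' @param calls an [sv_calls()] data frame.
#' @param read_length read length in bp (> 0).
#' @param reference_length contig length used for clamping (default: none).
#' @return A data frame with one row per call: `id`, the six region bounds
#'   (`core_start`, `core_end`, `ext_start`, `ext_end`, `vic_start`,
#'   `vic_end`) and `length`.
#' @export
derive_regions <- function(calls, read_length = 100, reference_length = Inf) {
  stopifnot(read_length > 0)
  if (any(calls$pos > reference_length))
    stop("derive_regions: call position beyond reference length: ",
         paste(calls$id[calls$pos > reference_length], collapse = ", "))
  L <- calls$length
  pad_v <- floor(L / 10)
  cl <- function(x) as.integer(clamp(x, 1, reference_length))
  data.frame(
    id = calls$id,
    core_start = cl(calls$pos - read_length),  core_end = cl(calls$end + read_length),
    ext_start  = cl(calls$pos - 2 * read_length), ext_end = cl(calls$end + 2 * read_length),
    vic_start  = cl(calls$pos - pad_v),        vic_end = cl(calls$end + pad_v),
    length = L, stringsAsFactors = FALSE)
}

#' Estimate library insert-size statistics from paired alignments
#'
#' The mean and standard deviation of the absolute observed template length
#' over pairs with both mates mapped and a non-zero TLEN. Pairs whose
#' template length lies more than 10 MADs from the median are excluded
#' first: discordant pairs straddling structural variants otherwise inflate
#' the scale estimate far beyond the library distribution. The standard
#' deviation uses the population denominator (n).
#'
#' @param alignments an alignment data frame from [read_alignments()], or a
#'   pair table from [build_pair_table()].
#' @return A list with `mu`, `sigma` and `source = "estimated"`.
#' @export
estimate_insert_stats <- function(alignments) {
  pairs <- if (!is.null(alignments$insert_size)) alignments
           else build_pair_table(alignments)
  ins <- pairs$insert_size[!is.na(pairs$insert_size) & pairs$insert_size > 0]
  if (length(ins) < 2)
    stop("estimate_insert_stats: fewer than 2 proper pairs; ",
         "supply mu and sigma explicitly")
  md <- stats::median(ins)
  dev <- stats::mad(ins)
  if (dev > 0) ins <- ins[abs(ins - md) <= 10 * dev]
  mu <- mean(ins)
  sigma <- sqrt(mean((ins - mu)^2))
  if (sigma <= 0)
    stop("estimate_insert_stats: zero insert-size variance; ",
         "supply sigma explicitly")
  list(mu = mu, sigma = sigma, source = "estimated")
}

#' Insert-size statistics supplied by the user
#'
#' @param mu mean library insert size (bp).
#' @param sigma standard deviation (bp), > 0.
#' @return A list with `mu`, `sigma` and `source = "user"`.
#' @export
insert_stats <- function(mu, sigma) {
  stopifnot(sigma > 0)
  list(mu = mu, sigma = sigma, source = "user")
}

#' Collect the alignment records and read pairs of one region
#'
#' A record belongs to the region iff its POS (leftmost mapped base; for
#' unmapped records the anchoring mate position stored in POS) lies in
#' `[start, stop]` inclusive. Pairs are joined by QNAME over the whole file;
#' a pair is returned when at least one mate's POS is in-region, with
#' per-mate membership indicators.
#'
#' @param alignments alignment data frame from [read_alignments()].
#' @param start,stop 1-based closed region bounds.
#' @param pair_table optional precomputed [build_pair_table()] result (saves
#'   recomputation when scanning many regions of one file).
#' @return A list with `records` (in-region rows of `alignments`) and
#'   `pairs` (pair-table rows with logical columns `in1`, `in2`).
#' @export
collect_region_records <- function(alignments, start, stop, pair_table = NULL) {
  inreg <- !is.na(alignments$pos) & alignments$pos >= start & alignments$pos <= stop
  if (is.null(pair_table)) pair_table <- build_pair_table(alignments)
  p1 <- !is.na(pair_table$pos1) & pair_table$pos1 >= start & pair_table$pos1 <= stop
  p2 <- !is.na(pair_table$pos2) & pair_table$pos2 >= start & pair_table$pos2 <= stop
  keep <- p1 | p2
  pairs <- pair_table[keep, , drop = FALSE]
  pairs$in1 <- p1[keep]
  pairs$in2 <- p2[keep]
  list(records = alignments[inreg, , drop = FALSE], pairs = pairs)
}

#' Join alignment records into one row per read pair
#'
#' Mates are matched by QNAME; the first/second mate is identified by FLAG
#' bits 0x40/0x80. QNAMEs observed once yield a pair row with `NA` second
#' mate; such pairs contribute only to read-level features downstream.
#'
#' @param alignments alignment data frame from [read_alignments()].
#' @return A data frame with one row per QNAME: `qname`, per-mate
#'   `pos`, `cigar`, `mapq`, `flag`, `mapped` columns (suffix 1/2) and
#'   `insert_size` (absolute TLEN when both mates are mapped, else `NA`).
#' @export
build_pair_table <- function(alignments) {
  a <- alignments
  is2 <- bitwAnd(a$flag, 128L) != 0L
  f <- a[!is2, , drop = FALSE]
  s <- a[is2, , drop = FALSE]
  ## qnames only ever seen as a second mate are promoted to slot 1
  orphan2 <- !(s$qname %in% f$qname)
  if (any(orphan2)) {
    f <- rbind(f, s[orphan2, , drop = FALSE])
    s <- s[!orphan2, , drop = FALSE]
  }
  j <- match(f$qname, s$qname)
  m1 <- !f$unmapped
  m2 <- !is.na(j) & !s$unmapped[j]
  tl <- abs(f$tlen)
  insert <- ifelse(m1 & m2, tl, NA_real_)
  data.frame(
    qname = f$qname,
    pos1 = f$pos, cigar1 = f$cigar, mapq1 = f$mapq, flag1 = f$flag, mapped1 = m1,
    pos2 = s$pos[j], cigar2 = s$cigar[j], mapq2 = s$mapq[j], flag2 = s$flag[j],
    mapped2 = m2,
    insert_size = insert,
    stringsAsFactors = FALSE)
}
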