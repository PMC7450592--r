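## Alignment file I/O. Reading goes through Rsamtools (SAM text is converted
## to BAM first); writing is a plain-text SAM emitter for the simulator's
## emulated alignments.

#' Read alignment records from a SAM or BAM file
#'
#' Returns the per-record fields the feature extractor consumes. SAM text is
#' converted to BAM with `Rsamtools::asBam()` and then scanned; `.bam` input
#' is scanned directly. The whole file is read (the package's region
#' membership test is by POS over an in-memory table, mirroring a full scan,
#' so no index is required).
#'
#' @param path path to a `.sam` or `.bam` file with valid `@HD`/`@SQ` headers.
#' @return A data frame with columns `qname, flag, rname, pos, mapq, cigar,
#'   mpos, tlen, unmapped`. `pos` is the 1-based leftmost mapped base (for
#'   unmapped records, the anchoring mate position when present). Missing
#'   MAPQ is 0; missing CIGAR is `"*"`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("read_alignments: no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "mpos", "isize")))[[1]]
  flag <- as.integer(res$flag)
  mapq <- as.integer(res$mapq); mapq[is.na(mapq)] <- 0L
  cig <- as.character(res$cigar); cig[is.na(cig)] <- "*"
  pos <- as.integer(res$pos)
  unmapped <- bitwAnd(flag, 4L) != 0L
  ## Rsamtools masks POS on unmapped records; restore the SAM placement
  ## (the anchoring mate position) so region membership by POS still works
  fix <- unmapped & is.na(pos) & !is.na(res$mpos)
  pos[fix] <- as.integer(res$mpos[fix])
  ## SAM stores unmapped mates at the anchor's POS; scanBam reports NA pos for
  ## unmapped records only when POS was 0 in the file.
  tlen <- as.integer(res$isize); tlen[is.na(tlen)] <- 0L
  mpos <- as.integer(res$mpos)
  data.frame(qname = as.character(res$qname), flag = flag,
             rname = as.character(res$rname), pos = pos, mapq = mapq,
             cigar = cig, mpos = mpos, tlen = tlen, unmapped = unmapped,
             stringsAsFactors = FALSE)
}

#' Write alignment records as a SAM file
#'
#' @param records data frame with columns `qname, flag, pos, mapq, cigar,
#'   mpos, tlen` and optionally `seq`, `qual` (default `"*"`). Records are
#'   written in coordinate order.
#' @param path output `.sam` path.
#' @param chrom contig name for the `@SQ` header.
#' @param reference_length contig length for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, chrom, reference_length) {
  r <- records[order(records$pos, method = "radix"), , drop = FALSE]
  seqs <- r$seq %||% rep("*", nrow(r))
  quals <- r$qual %||% rep("*", nrow(r))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(reference_length)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
                  r$qname, r$flag, chrom, r$pos, r$mapq, r$cigar,
                  r$mpos, r$tlen, seqs, quals)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write paired reads as two FASTQ files
#'
#' @param qname read-pair names.
#' @param seq1,seq2 read sequences (second mate as sequenced, i.e. already
#'   reverse-complemented relative to the fragment).
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with constant quality `I`.
#' @return The two paths, invisibly.
#' @export
write_fastq_pair <- function(qname, seq1, seq2, prefix) {
  emit <- function(seqs, path) {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    writeLines(as.vector(rbind(paste0("@", qname), seqs, "+", qual)), path)
    path
  }
  p1 <- emit(seq1, paste0(prefix, "_1.fastq"))
  p2 <- emit(seq2, paste0(prefix, "_2.fastq"))
  invisible(c(p1, p2))
}

## reverse complement of a vector of sequences (plain character)
revcomp <- function(x) {
  vapply(x, function(s)
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}
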