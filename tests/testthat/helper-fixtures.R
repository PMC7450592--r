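# Fixture builders and independent text-scan oracles.
#
# The oracles parse SAM text column-by-column (FLAG = col 2, POS = col 4,
# MAPQ = col 5, CIGAR = col 6, TLEN = col 9), deliberately sharing no code
# with the package's Rsamtools-based path.

# one SAM record line
sam_line <- function(qname, flag, pos, mapq, cigar, mpos, tlen,
                     rname = "sim1") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
          qname, flag, rname, pos, mapq, cigar, mpos, tlen)
}

# a small SAM file: list of record lines -> path
write_sam_fixture <- function(lines, ref_len = 100000, rname = "sim1") {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", rname, ref_len))
  writeLines(c(hdr, lines), path)
  path
}

# a deterministic 20-record mixed fixture around positions 900-1600:
# proper pairs, a long-insert pair, clipped records, an unmapped record,
# flags 83/163/99/147 and a compound flag 339
mixed_fixture_lines <- function() {
  c(
    sam_line("p1", 99, 1000, 60, "100M", 1400, 500),
    sam_line("p1", 147, 1400, 60, "100M", 1000, -500),
    sam_line("p2", 83, 1450, 60, "100M", 1050, -500),
    sam_line("p2", 163, 1050, 60, "100M", 1450, 500),
    sam_line("p3", 97, 1100, 30, "60M40S", 3100, 2100),   # long insert
    sam_line("p3", 145, 3100, 30, "100M", 1100, -2100),
    sam_line("p4", 99, 1200, 60, "100M", 1600, 500),
    sam_line("p4", 147, 1600, 30, "40S60M", 1200, -500),
    sam_line("p5", 73, 1250, 60, "100M", 1250, 0),        # mate unmapped
    sam_line("p5", 133, 1250, 0, "*", 1250, 0),
    sam_line("p6", 339, 1300, 60, "100M", 1700, 500),     # secondary 83-like
    sam_line("p6", 147, 1700, 60, "100M", 1300, -500),
    sam_line("p7", 99, 900, 60, "100M", 1290, 490),
    sam_line("p7", 147, 1290, 60, "100M", 900, -490),
    sam_line("p8", 99, 1500, 15, "100M", 1950, 550),      # abnormal insert
    sam_line("p8", 147, 1950, 15, "100M", 1500, -550),
    sam_line("p9", 99, 600, 60, "100M", 1010, 510),       # mate in region
    sam_line("p9", 147, 1010, 60, "100M", 600, -510),
    sam_line("p10", 99, 1550, 60, "100M", 5000, 3550),
    sam_line("p10", 147, 5000, 60, "100M", 1550, -3550)
  )
}

# ---- independent text-scan oracle ------------------------------------------

parse_sam_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    qname = vapply(f, `[`, "", 1),
    flag = as.integer(vapply(f, `[`, "", 2)),
    pos = as.integer(vapply(f, `[`, "", 4)),
    mapq = as.integer(vapply(f, `[`, "", 5)),
    cigar = vapply(f, `[`, "", 6),
    tlen = as.integer(vapply(f, `[`, "", 9)),
    stringsAsFactors = FALSE)
}

# all fifteen features for one call, from raw SAM text
oracle_features <- function(path, pos, end, mu, sigma, read_length = 100,
                            ref_len = Inf) {
  d <- parse_sam_text(path)
  d$unmapped <- bitwAnd(d$flag, 4L) != 0L
  L <- abs(pos - end)
  cl <- function(x) min(max(x, 1), ref_len)
  cs <- cl(pos - read_length); ce <- cl(end + read_length)
  es <- cl(pos - 2 * read_length); ee <- cl(end + 2 * read_length)
  vs <- cl(pos - floor(L / 10)); ve <- cl(end + floor(L / 10))
  token <- paste0(read_length, "M")
  inreg <- d$pos >= cs & d$pos <= ce

  # pair bookkeeping by qname
  qn <- unique(d$qname)
  pair <- lapply(qn, function(q) d[d$qname == q, , drop = FALSE])
  names(pair) <- qn
  pair_in <- vapply(pair, function(p) any(p$pos >= cs & p$pos <= ce), TRUE)

  normal <- 0; abnormal <- 0; fully <- 0; split <- 0
  for (q in qn[pair_in]) {
    p <- pair[[q]]
    if (nrow(p) != 2 || any(p$unmapped)) next
    ins <- abs(p$tlen[1])
    if (ins >= mu - 3 * sigma && ins <= mu + 3 * sigma) normal <- normal + 1
    else abnormal <- abnormal + 1
    if (all(p$cigar == token)) fully <- fully + 1
    memb <- p$pos >= cs & p$pos <= ce
    if (sum(memb) == 1) split <- split + 1
  }
  single <- 0; incompl <- 0
  for (i in which(inreg & !d$unmapped)) {
    if (d$cigar[i] != token) { incompl <- incompl + 1; next }
    p <- pair[[d$qname[i]]]
    mate <- p[p$flag != d$flag[i] | p$pos != d$pos[i], , drop = FALSE]
    ok <- nrow(mate) >= 1 && !mate$unmapped[1] && mate$cigar[1] == token
    if (!ok) single <- single + 1
  }
  unm <- sum(inreg & d$unmapped)
  mapq_sum <- sum(d$mapq[inreg])
  n_mapped <- sum(inreg & !d$unmapped)
  den <- if (L > 0) L else ce - cs + 1
  qmax <- max(d$mapq)
  D <- n_mapped / den
  wrd <- sum(d$mapq[inreg & !d$unmapped] / qmax) / den
  inext <- d$pos >= es & d$pos <= ee
  ewrd <- sum(d$mapq[inext & !d$unmapped] / qmax) / den
  affected <- sum(d$pos >= vs & d$pos <= ve)
  dir1 <- sum(d$flag[inreg] == 83L)
  dir2 <- sum(d$flag[inreg] == 163L)
  c(abnormal_read = abnormal, normal_read = normal,
    incompletely_mapped = incompl, fully_mapped = fully,
    split_mapped = split, single_mapped = single, unmapped = unm,
    mapq_sum = mapq_sum, read_depth = D, weighted_read_depth = wrd,
    ext_weighted_read_depth = ewrd, affected_reads = affected,
    variant_length = L, direction1 = dir1, direction2 = dir2)
}

# small simulated dataset shared across tests (cheap: 120 calls, 300 kbp)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(region_length = 4.5e5,
                        n_calls = c(N = 24, G1 = 32, G2 = 32, G3 = 20, G4 = 12),
                        coverage = 10, copy_number = 3, seed = 424)
      cache <<- simulate_sv_data(cfg, write_fastq = FALSE)
    }
    cache
  }
})
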