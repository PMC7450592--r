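## Diploid genome + paired-end read simulator.
##
## Plants SVs (INS/DEL/INV/CPX) in five genotype classes, realizes the
## co-occurring CNV of classes G3/G4 as a tandem duplication bringing one
## haplotype's segment to `copy_number` copies, adds SNVs at an elevated rate
## near variants, samples paired-end fragments uniformly along each
## haplotype, and emulates the alignment signals (CIGAR, FLAG, MAPQ, TLEN) a
## mapper would produce, via exact haplotype-to-reference coordinate maps.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions used throughout the package's
#' evaluation: a 1 Mbp reference with 300 planted calls split 60/80/80/50/30
#' over the classes N/G1/G2/G3/G4, SV lengths 0.5--5 kbp, CNV lengths 1--5
#' kbp, 100 bp paired-end reads with insert size Normal(500, 15), base error
#' rate 0.005, and SNV rates 0.01 within an elevated window (variant length
#' + 1000 bp) versus 0.0001 background.
#'
#' @param region_length reference length in bp.
#' @param n_calls named integer vector of per-class call counts
#'   (names `N, G1, G2, G3, G4`).
#' @param sv_length_range SV length bounds in bp.
#' @param cnv_length_range CNV length bounds in bp (classes G3/G4).
#' @param copy_number total copies of the CNV segment on the affected
#'   haplotype (>= 2).
#' @param coverage total sequencing depth (both haplotypes combined).
#' @param read_length read length in bp.
#' @param insert_mu,insert_sigma insert-size Normal distribution (bp).
#' @param base_error_rate per-base sequencing error probability.
#' @param elevated_snv_rate,background_snv_rate per-bp SNV substitution
#'   probabilities inside/outside elevated windows.
#' @param elevated_pad bp added on each side of a variant to form its
#'   elevated SNV window (500 each side = window 1000 bp longer than the
#'   variant).
#' @param cpx_nearby_fraction probability that a complex-indel insert is
#'   copied from the adjacent reference rather than novel sequence.
#' @param purity fraction of fragments drawn from the variant-bearing
#'   genome; the remainder come from the plain reference (tumor purity; 1 =
#'   pure).
#' @param chrom contig name used in all outputs.
#' @param seed integer seed; every simulation entry point is deterministic
#'   given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(region_length = 1e6,
                       n_calls = c(N = 60, G1 = 80, G2 = 80, G3 = 50, G4 = 30),
                       sv_length_range = c(500, 5000),
                       cnv_length_range = c(1000, 5000),
                       copy_number = 3,
                       coverage = 10,
                       read_length = 100,
                       insert_mu = 500, insert_sigma = 15,
                       base_error_rate = 0.005,
                       elevated_snv_rate = 0.01,
                       background_snv_rate = 1e-4,
                       elevated_pad = 500,
                       cpx_nearby_fraction = 0.25,
                       purity = 1,
                       chrom = "sim1",
                       seed = NULL) {
  if (is.null(names(n_calls))) names(n_calls) <- GENOTYPE_CLASSES
  stopifnot(all(GENOTYPE_CLASSES %in% names(n_calls)),
            all(n_calls >= 0), copy_number >= 2, coverage > 0,
            read_length > 0, insert_sigma > 0,
            all(c(base_error_rate, elevated_snv_rate, background_snv_rate,
                  cpx_nearby_fraction, purity) >= 0),
            all(c(base_error_rate, elevated_snv_rate, background_snv_rate,
                  cpx_nearby_fraction, purity) <= 1))
  cfg <- list(region_length = as.integer(region_length),
              n_calls = n_calls[GENOTYPE_CLASSES],
              sv_length_range = as.integer(sv_length_range),
              cnv_length_range = as.integer(cnv_length_range),
              copy_number = as.integer(copy_number),
              coverage = coverage, read_length = as.integer(read_length),
              insert_mu = insert_mu, insert_sigma = insert_sigma,
              base_error_rate = base_error_rate,
              elevated_snv_rate = elevated_snv_rate,
              background_snv_rate = background_snv_rate,
              elevated_pad = as.integer(elevated_pad),
              cpx_nearby_fraction = cpx_nearby_fraction,
              purity = purity, chrom = chrom, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

random_reference <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Plant structural variants and CNVs on a diploid genome
#'
#' Draws non-overlapping placements uniformly along the reference (every
#' call's footprint, including its elevated SNV window and a working margin,
#' is disjoint from all others), assigns each call an SV type uniformly over
#' INS/DEL/INV/CPX and a genotype class per `cfg$n_calls`, and builds the
#' per-haplotype event lists. G3/G4 CNVs are tandem duplications bringing
#' the affected haplotype segment to `cfg$copy_number` copies; a complex
#' indel is a deletion plus an insertion at the same locus whose content is
#' copied from the adjacent reference with probability
#' `cfg$cpx_nearby_fraction` and novel otherwise.
#'
#' @param reference character vector of single bases.
#' @param cfg a [sim_config()].
#' @return A list with `truth` (an [sv_calls()] frame with `gtclass` and CNV
#'   bookkeeping columns) and per-haplotype event lists `events_h1`,
#'   `events_h2`.
#' @export
plant_variants <- function(reference, cfg) {
  n_ref <- length(reference)
  counts <- cfg$n_calls
  nc <- sum(counts)
  gts <- sample(rep(GENOTYPE_CLASSES, times = counts))
  if (nc == 0) stop("plant_variants: no calls requested")

  svr <- cfg$sv_length_range; cnvr <- cfg$cnv_length_range
  has_cnv <- gts %in% c("G3", "G4")
  ## Variant/CNV footprints (plus the extended feature region) are kept
  ## disjoint; elevated SNV windows may overlap neighbouring slots -- at the
  ## default density (300 calls, 0.5-5 kb, per 1 Mbp) fully disjoint windows
  ## do not fit. Packing redraws lengths on the rare infeasible draw.
  margin <- 200L
  edge <- 1000L
  for (attempt in 1:10) {
    types <- sample(c("INS", "DEL", "INV", "CPX"), nc, replace = TRUE)
    cnvlen <- ifelse(has_cnv, floor(stats::runif(nc, cnvr[1], cnvr[2] + 1)), 0L)
    svmax <- ifelse(has_cnv, pmin(svr[2], cnvlen), svr[2])
    svlen <- floor(stats::runif(nc, svr[1], svmax + 1))
    span <- ifelse(has_cnv, cnvlen, svlen)
    slot <- span + 2L * margin
    slack <- n_ref - 2 * edge - sum(slot)
    if (slack >= 0) break
    if (attempt == 10)
      stop("plant_variants: region too small for the requested calls; ",
           "increase region_length or reduce counts/lengths")
  }
  gaps <- floor(diff(c(0, sort(stats::runif(nc)))) * slack)
  span_start <- edge + cumsum(c(0, slot[-nc])) + cumsum(gaps) +
    margin + 1L
  ## SV interval within its (possibly CNV-sized) span
  off <- ifelse(has_cnv, floor(stats::runif(nc) * (cnvlen - svlen + 1)), 0L)
  pos <- as.integer(span_start + off)
  end <- as.integer(pos + svlen)
  cstart <- as.integer(ifelse(has_cnv, span_start, NA))
  cend <- as.integer(ifelse(has_cnv, span_start + cnvlen, NA))

  hap <- sample(1:2, nc, replace = TRUE)   # variant-bearing haplotype (G2-4)
  truth <- sv_calls(sprintf("sv%03d", seq_len(nc)), cfg$chrom, pos, end, types)
  truth$gtclass <- gts
  truth$hap <- hap
  truth$cnv_start <- cstart
  truth$cnv_end <- cend
  truth$copy_number <- ifelse(has_cnv, cfg$copy_number, 2L)

  make_insert <- function(i) {
    L <- svlen[i]
    if (types[i] == "CPX" && stats::runif(1) < cfg$cpx_nearby_fraction) {
      m <- min(L, 1000L)
      list(nearby = TRUE, src_start = pos[i] - m, src_len = m,
           tail_seq = random_bases(L - m))
    } else list(nearby = FALSE, seq = random_bases(L))
  }

  ev1 <- list(); ev2 <- list()
  for (i in seq_len(nc)) {
    g <- gts[i]
    if (g == "N") next
    ins <- if (types[i] %in% c("INS", "CPX")) make_insert(i) else NULL
    sv <- list(kind = "sv", type = types[i], pos = pos[i], end = end[i],
               svlen = svlen[i], insert = ins)
    if (g == "G1") { ev1[[length(ev1) + 1]] <- sv; ev2[[length(ev2) + 1]] <- sv }
    else if (g == "G2") {
      if (hap[i] == 1) ev1[[length(ev1) + 1]] <- sv else ev2[[length(ev2) + 1]] <- sv
    } else if (g == "G3") {
      dup <- list(kind = "dupsv", sv = sv, cstart = cstart[i], cend = cend[i],
                  n = cfg$copy_number)
      if (hap[i] == 1) ev1[[length(ev1) + 1]] <- dup else ev2[[length(ev2) + 1]] <- dup
    } else if (g == "G4") {
      dup <- list(kind = "dup", cstart = cstart[i], cend = cend[i],
                  n = cfg$copy_number)
      if (hap[i] == 1) { ev1[[length(ev1) + 1]] <- sv; ev2[[length(ev2) + 1]] <- dup }
      else             { ev2[[length(ev2) + 1]] <- sv; ev1[[length(ev1) + 1]] <- dup }
    }
  }
  sort_ev <- function(ev) {
    if (!length(ev)) return(ev)
    key <- vapply(ev, function(e) if (e$kind == "sv") e$pos else e$cstart, numeric(1))
    ev[order(key)]
  }
  list(truth = truth, events_h1 = sort_ev(ev1), events_h2 = sort_ev(ev2))
}

#' Plant SNVs on each haplotype
#'
#' Per-base substitution applied independently per haplotype: probability
#' `cfg$elevated_snv_rate` inside the elevated windows (each planted variant
#' padded by `cfg$elevated_pad` on both sides, i.e. a window 1000 bp longer
#' than the variant at the default), `cfg$background_snv_rate` elsewhere.
#' Substituted bases are drawn uniformly from the three alternatives.
#'
#' @param reference character vector of single bases.
#' @param truth truth frame from [plant_variants()] (rows with
#'   `gtclass != "N"` define elevated windows); may be `NULL` for
#'   background-only planting.
#' @param cfg a [sim_config()].
#' @return list with mutated per-haplotype references `h1`, `h2` (character
#'   vectors, reference coordinates) and SNV counts `n_h1`, `n_h2`.
#' @export
plant_snvs <- function(reference, truth, cfg) {
  n <- length(reference)
  rate <- rep(cfg$background_snv_rate, n)
  if (!is.null(truth)) {
    vr <- truth[truth$gtclass != "N", , drop = FALSE]
    for (i in seq_len(nrow(vr))) {
      w <- clamp(c(vr$pos[i] - cfg$elevated_pad, vr$end[i] + cfg$elevated_pad), 1, n)
      rate[w[1]:w[2]] <- cfg$elevated_snv_rate
    }
  }
  mutate <- function() {
    h <- reference
    idx <- which(stats::runif(n) < rate)
    if (length(idx)) {
      cur <- h[idx]
      shift <- sample(1:3, length(idx), replace = TRUE)
      bases <- c("A", "C", "G", "T")
      h[idx] <- bases[(match(cur, bases) - 1 + shift) %% 4 + 1]
    }
    list(h = h, n = length(idx))
  }
  m1 <- mutate(); m2 <- mutate()
  list(h1 = m1$h, h2 = m2$h, n_h1 = m1$n, n_h2 = m2$n)
}

## Assemble one haplotype from its event list: returns the haplotype
## sequence and the block map used to emulate alignment. Blocks are maximal
## runs mapping contiguously to the reference (strand +/-) or novel inserts;
## every block junction is a true breakpoint.
build_haplotype <- function(ref_chars, events) {
  blocks <- vector("list", 0)
  add_ref <- function(rs, re, strand = 1L) {
    if (re < rs) return()
    blocks[[length(blocks) + 1]] <<- list(ref_start = rs, ref_end = re,
                                          strand = strand, seq = NULL)
  }
  add_novel <- function(seq) {
    if (!length(seq)) return()
    blocks[[length(blocks) + 1]] <<- list(ref_start = NA_integer_,
                                          ref_end = NA_integer_,
                                          strand = 1L, seq = seq)
  }
  emit_insert <- function(ins) {
    if (ins$nearby) {
      add_ref(ins$src_start, ins$src_start + ins$src_len - 1L)
      add_novel(ins$tail_seq)
    } else add_novel(ins$seq)
  }
  ## apply one SV whose reference span starts at its pos; returns the
  ## reference coordinate where unaltered sequence resumes
  emit_sv <- function(sv) {
    switch(sv$type,
      DEL = sv$end + 1L,
      INS = { emit_insert(sv$insert); sv$pos },
      INV = { add_ref(sv$pos, sv$end, -1L); sv$end + 1L },
      CPX = { emit_insert(sv$insert); sv$end + 1L })
  }
  cursor <- 1L
  for (ev in events) {
    estart <- if (ev$kind == "sv") ev$pos else ev$cstart
    add_ref(cursor, estart - 1L)
    if (ev$kind == "sv") {
      cursor <- emit_sv(ev)
    } else if (ev$kind == "dup") {
      for (k in seq_len(ev$n)) add_ref(ev$cstart, ev$cend)
      cursor <- ev$cend + 1L
    } else { # dupsv: each copy carries the variant
      for (k in seq_len(ev$n)) {
        add_ref(ev$cstart, ev$sv$pos - 1L)
        resume <- emit_sv(ev$sv)
        add_ref(resume, ev$cend)
      }
      cursor <- ev$cend + 1L
    }
  }
  add_ref(cursor, length(ref_chars))

  lens <- vapply(blocks, function(b)
    if (is.na(b$ref_start)) length(b$seq) else b$ref_end - b$ref_start + 1L,
    numeric(1))
  keep <- lens > 0
  blocks <- blocks[keep]; lens <- lens[keep]
  hap_end <- cumsum(lens)
  hap_start <- hap_end - lens + 1
  seq_parts <- lapply(blocks, function(b) {
    if (is.na(b$ref_start)) b$seq
    else if (b$strand == 1L) ref_chars[b$ref_start:b$ref_end]
    else chartr("ACGT", "TGCA", rev(ref_chars[b$ref_start:b$ref_end]))
  })
  map <- data.frame(
    hap_start = hap_start, hap_end = hap_end,
    ref_start = vapply(blocks, function(b) as.integer(b$ref_start %||% NA), integer(1)),
    ref_end = vapply(blocks, function(b) as.integer(b$ref_end %||% NA), integer(1)),
    strand = vapply(blocks, function(b) as.integer(b$strand), integer(1)),
    novel = vapply(blocks, function(b) is.na(b$ref_start), logical(1)))
  list(seq = unlist(seq_parts, use.names = FALSE), map = map)
}

#' Build a diploid genome with planted variants and SNVs
#'
#' Runs [plant_variants()] and [plant_snvs()] and assembles both haplotypes
#' with their haplotype-to-reference coordinate maps.
#'
#' @param cfg a [sim_config()].
#' @param reference optional character vector of single bases (e.g. a FASTA
#'   slice); by default a seeded uniform-random sequence of
#'   `cfg$region_length` bp.
#' @return A list of class `diploid_genome`: `reference`, `h1`, `h2` (each
#'   haplotype a list with `seq` and block `map`), `truth`, `snv_counts`.
#' @export
simulate_genome <- function(cfg, reference = NULL) {
  with_seed(cfg$seed, {
    if (is.null(reference)) reference <- random_reference(cfg$region_length)
    pv <- plant_variants(reference, cfg)
    snv <- plant_snvs(reference, pv$truth, cfg)
    g <- list(reference = reference,
              h1 = build_haplotype(snv$h1, pv$events_h1),
              h2 = build_haplotype(snv$h2, pv$events_h2),
              truth = pv$truth,
              snv_counts = c(h1 = snv$n_h1, h2 = snv$n_h2),
              chrom = cfg$chrom)
    class(g) <- "diploid_genome"
    g
  })
}

#' Sample paired-end fragments along the haplotypes
#'
#' Fragment starts are uniform along each haplotype (CNV-amplified segments
#' are therefore over-sampled in reference coordinates in proportion to
#' their copy number); insert lengths are Normal(`insert_mu`,
#' `insert_sigma`) rounded, redrawn while shorter than two read lengths or
#' longer than the haplotype. The pair count per haplotype gives expected
#' per-haplotype depth `coverage/2`. With `purity < 1`, the complementary
#' fraction of fragments is drawn from the plain reference (haplotype 0).
#'
#' @param genome a [simulate_genome()] result.
#' @param cfg a [sim_config()].
#' @return Data frame of fragments: `qname, hap, start, insert, swap`
#'   (`swap` marks pairs whose first-in-pair mate is the rightmost, reverse
#'   read, so both read1-forward and read1-reverse pair layouts occur).
#' @export
sample_read_pairs <- function(genome, cfg) {
  rl <- cfg$read_length
  lens <- c(length(genome$h1$seq), length(genome$h2$seq))
  n_h <- round((cfg$coverage / 2) * lens / (2 * rl))
  hap <- rep.int(1:2, n_h)
  n <- length(hap)
  if (cfg$purity < 1) {
    pure <- stats::runif(n) < cfg$purity
    hap[!pure] <- 0L             # plain reference fragments
  }
  hlen <- c(length(genome$reference), lens)[hap + 1L]
  insert <- round(stats::rnorm(n, cfg$insert_mu, cfg$insert_sigma))
  bad <- which(insert < 2 * rl | insert > hlen)
  while (length(bad)) {
    insert[bad] <- round(stats::rnorm(length(bad), cfg$insert_mu, cfg$insert_sigma))
    bad <- bad[insert[bad] < 2 * rl | insert[bad] > hlen[bad]]
  }
  start <- 1L + floor(stats::runif(n) * (hlen - insert + 1))
  data.frame(qname = sprintf("sim%06d", seq_len(n)),
             hap = hap, start = as.integer(start), insert = as.integer(insert),
             swap = stats::runif(n) < 0.5)
}

## Vectorized read mapping through a block map. a,b: haplotype interval of
## each read. Returns pos/mapq/cigar/mlen/rev-strand-flip/mapped vectors.
## Rules: read within one reference block -> full-length match, MAPQ 60;
## read crossing a breakpoint with a >= `anchor_min` bp anchor -> soft-
## clipped on the shorter side, MAPQ 30; read confined to novel sequence or
## without a sufficient anchor -> unmapped.
map_reads <- function(a, b, map, read_length, anchor_min = 20L) {
  n <- length(a)
  ia <- findInterval(a, map$hap_start)
  ib <- findInterval(b, map$hap_start)
  pos <- rep(NA_integer_, n); mapq <- integer(n)
  mlen <- integer(n); clip_left <- logical(n)
  flip <- logical(n); mapped <- logical(n)

  one <- ia == ib
  full <- one & !map$novel[ia]
  ## full-length match
  if (any(full)) {
    i <- which(full); bi <- ia[i]
    fwd <- map$strand[bi] == 1L
    d <- a[i] - map$hap_start[bi]
    pos[i] <- ifelse(fwd, map$ref_start[bi] + d,
                     map$ref_end[bi] - (b[i] - map$hap_start[bi]))
    flip[i] <- !fwd
    mapped[i] <- TRUE; mapq[i] <- 60L; mlen[i] <- read_length
  }
  ## breakpoint-crossing: anchor on the longer mappable side
  cross <- !one
  if (any(cross)) {
    i <- which(cross)
    la <- map$hap_end[ia[i]] - a[i] + 1              # bases in first block
    lb <- b[i] - map$hap_start[ib[i]] + 1            # bases in last block
    la[map$novel[ia[i]]] <- 0L
    lb[map$novel[ib[i]]] <- 0L
    use_a <- la >= lb
    alen <- ifelse(use_a, la, lb)
    abl <- ifelse(use_a, ia[i], ib[i])
    ok <- alen >= anchor_min
    j <- i[ok]; bi <- abl[ok]; x <- as.integer(alen[ok]); ua <- use_a[ok]
    if (length(j)) {
      fwd <- map$strand[bi] == 1L
      ## anchor haplotype interval
      as_ <- ifelse(ua, a[j], b[j] - x + 1)
      ae_ <- ifelse(ua, a[j] + x - 1, b[j])
      d1 <- as_ - map$hap_start[bi]
      d2 <- ae_ - map$hap_start[bi]
      pos[j] <- ifelse(fwd, map$ref_start[bi] + d1, map$ref_end[bi] - d2)
      flip[j] <- !fwd
      mapped[j] <- TRUE; mapq[j] <- 30L; mlen[j] <- x
      ## clip side in reference orientation: anchor-at-read-start maps the
      ## clip to the right on the forward strand, to the left when flipped
      clip_left[j] <- xor(!ua, !fwd)
    }
  }
  cigar <- rep("*", n)
  fullm <- mapped & mlen == read_length
  cigar[fullm] <- paste0(read_length, "M")
  part <- mapped & !fullm
  if (any(part)) {
    s <- read_length - mlen[part]
    cigar[part] <- ifelse(clip_left[part],
                          paste0(s, "S", mlen[part], "M"),
                          paste0(mlen[part], "M", s, "S"))
  }
  list(pos = pos, mapq = mapq, cigar = cigar, mlen = mlen,
       flip = flip, mapped = mapped)
}

#' Emulate the alignment of sampled fragments
#'
#' Maps each read deterministically through the haplotype coordinate maps
#' (see the package vignette for the rules: full-length match / soft-clipped
#' breakpoint anchor / unmapped, MAPQ tiers 60/30/0), sets SAM FLAG bits,
#' mate fields and TLEN as the distance between mapped mate ends on the
#' reference (so deletions inflate and insertions deflate the observed
#' insert size), and marks a pair proper iff it is FR-oriented with
#' `|TLEN|` within `insert_mu +/- 3 insert_sigma`.
#'
#' @param frags fragment frame from [sample_read_pairs()].
#' @param genome a [simulate_genome()] result.
#' @param cfg a [sim_config()].
#' @param include_seq if `TRUE`, attach read sequences (with base errors at
#'   `cfg$base_error_rate`) to the records; needed for FASTQ output.
#' @param sequences optional precomputed read sequences (internal) so the
#'   SAM and FASTQ outputs share one error realization.
#' @return Alignment records data frame (two rows per pair, both-unmapped
#'   pairs dropped) in the layout of [read_alignments()].
#' @export
emulate_alignment <- function(frags, genome, cfg, include_seq = FALSE,
                              sequences = NULL) {
  rl <- cfg$read_length
  identity_map <- data.frame(hap_start = 1, hap_end = length(genome$reference),
                             ref_start = 1L, ref_end = length(genome$reference),
                             strand = 1L, novel = FALSE)
  maps <- list(identity_map, genome$h1$map, genome$h2$map)
  n <- nrow(frags)
  mapL <- list(pos = rep(NA_integer_, n), mapq = integer(n),
               cigar = rep("*", n), mlen = integer(n),
               flip = logical(n), mapped = logical(n))
  mapR <- mapL
  aL <- frags$start; bL <- frags$start + rl - 1L
  aR <- frags$start + frags$insert - rl; bR <- frags$start + frags$insert - 1L
  for (h in 0:2) {
    idx <- which(frags$hap == h)
    if (!length(idx)) next
    m <- maps[[h + 1L]]
    rL <- map_reads(aL[idx], bL[idx], m, rl)
    rR <- map_reads(aR[idx], bR[idx], m, rl)
    for (f in names(mapL)) {
      mapL[[f]][idx] <- rL[[f]]
      mapR[[f]][idx] <- rR[[f]]
    }
  }
  ## reference strand: left read sequenced forward, right read sequenced as
  ## reverse complement; an inverted block flips the mapped strand
  revL <- mapL$flip
  revR <- !mapR$flip
  endL <- mapL$pos + mapL$mlen - 1L
  endR <- mapR$pos + mapR$mlen - 1L
  both <- mapL$mapped & mapR$mapped
  lo <- pmin(mapL$pos, mapR$pos)
  hi <- pmax(endL, endR)
  tl <- ifelse(both, hi - lo + 1L, 0L)
  fr <- both & (revL != revR) &
    ifelse(!revL, mapL$pos <= mapR$pos, mapR$pos <= mapL$pos)
  proper <- fr & abs(tl) >= cfg$insert_mu - 3 * cfg$insert_sigma &
    abs(tl) <= cfg$insert_mu + 3 * cfg$insert_sigma
  ## drop both-unmapped pairs (novel-insert interior; present in FASTQ only)
  keep <- mapL$mapped | mapR$mapped
  ## SAM convention: an unmapped mate is placed at its anchor's position
  posL <- ifelse(mapL$mapped, mapL$pos, mapR$pos)
  posR <- ifelse(mapR$mapped, mapR$pos, mapL$pos)
  L_first <- !frags$swap    # left read is first-in-pair unless swapped
  flag_one <- function(self_mapped, mate_mapped, self_rev, mate_rev, first) {
    1L +
      ifelse(proper & self_mapped & mate_mapped, 2L, 0L) +
      ifelse(!self_mapped, 4L, 0L) +
      ifelse(!mate_mapped, 8L, 0L) +
      ifelse(self_mapped & self_rev, 16L, 0L) +
      ifelse(mate_mapped & mate_rev, 32L, 0L) +
      ifelse(first, 64L, 128L)
  }
  flagL <- flag_one(mapL$mapped, mapR$mapped, revL, revR, L_first)
  flagR <- flag_one(mapR$mapped, mapL$mapped, revR, revL, !L_first)
  signL <- ifelse(both, ifelse(mapL$pos <= mapR$pos, tl, -tl), 0L)
  signR <- ifelse(both, ifelse(mapR$pos < mapL$pos, tl, -tl), 0L)

  seqL <- seqR <- NULL
  if (include_seq) {
    ## SAM stores SEQ reverse-complemented when FLAG 0x10 is set, i.e. in
    ## reference-forward orientation
    sq <- sequences %||% fragment_sequences(frags, genome, cfg)
    seqL <- ifelse(revL, revcomp_fast(sq$seq1), sq$seq1)
    seqR <- ifelse(revR, revcomp_fast(sq$seq2), sq$seq2)
  }
  rec <- function(flag, pos, mapq, cigar, mpos, tlen, mapped, seq) {
    d <- data.frame(qname = frags$qname, flag = flag, rname = genome$chrom,
                    pos = as.integer(pos), mapq = as.integer(mapq),
                    cigar = cigar, mpos = as.integer(mpos),
                    tlen = as.integer(tlen), unmapped = !mapped,
                    stringsAsFactors = FALSE)
    if (!is.null(seq)) d$seq <- seq
    d[keep, , drop = FALSE]
  }
  out <- rbind(
    rec(flagL, posL, mapL$mapq, mapL$cigar, posR, signL, mapL$mapped, seqL),
    rec(flagR, posR, mapR$mapq, mapR$cigar, posL, signR, mapR$mapped, seqR))
  out[order(out$pos, method = "radix"), , drop = FALSE]
}

## fast vectorized reverse complement (fixed-width reads)
revcomp_fast <- function(x) {
  if (!length(x)) return(x)
  m <- matrix(unlist(strsplit(chartr("ACGT", "TGCA", x), ""), use.names = FALSE),
              ncol = length(x))
  apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 2, paste, collapse = "")
}

## read sequences (as sequenced) with base errors applied
fragment_sequences <- function(frags, genome, cfg) {
  rl <- cfg$read_length
  seqs <- c(list(paste(genome$reference, collapse = "")),
            list(paste(genome$h1$seq, collapse = "")),
            list(paste(genome$h2$seq, collapse = "")))
  s1 <- character(nrow(frags)); s2 <- character(nrow(frags))
  for (h in 0:2) {
    idx <- which(frags$hap == h)
    if (!length(idx)) next
    st <- frags$start[idx]; ins <- frags$insert[idx]
    s1[idx] <- substring(seqs[[h + 1L]], st, st + rl - 1L)
    s2[idx] <- revcomp_fast(substring(seqs[[h + 1L]], st + ins - rl, st + ins - 1L))
  }
  apply_errors <- function(s) {
    if (cfg$base_error_rate <= 0) return(s)
    n_bases <- length(s) * rl
    n_err <- stats::rbinom(1, n_bases, cfg$base_error_rate)
    if (n_err == 0) return(s)
    at <- sample.int(n_bases, n_err)
    ri <- (at - 1L) %/% rl + 1L
    pi <- (at - 1L) %% rl + 1L
    for (k in seq_len(n_err)) {
      cur <- substr(s[ri[k]], pi[k], pi[k])
      alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      substr(s[ri[k]], pi[k], pi[k]) <- alt
    }
    s
  }
  list(seq1 = apply_errors(s1), seq2 = apply_errors(s2))
}

#' Simulate a full dataset: genome, reads, emulated alignments, truth set
#'
#' Orchestrates [simulate_genome()], [sample_read_pairs()] and
#' [emulate_alignment()]. With `out_prefix`, writes `<prefix>.truth.vcf`,
#' `<prefix>.sam` (and `.bam` when requested), paired FASTQ and a JSON
#' sidecar of the configuration.
#'
#' @param cfg a [sim_config()]; `cfg$seed` drives all randomness.
#' @param reference optional reference (character vector of bases).
#' @param out_prefix optional output path prefix.
#' @param write_bam also convert the SAM to BAM via Rsamtools.
#' @param write_fastq write paired FASTQ (implies sequence generation).
#' @return list of class `sv_simulation`: `truth` ([sv_calls()] with
#'   `gtclass`), `alignments` (records frame), `genome`, `config`, `paths`.
#' @export
simulate_sv_data <- function(cfg, reference = NULL, out_prefix = NULL,
                             write_bam = FALSE, write_fastq = !is.null(out_prefix)) {
  genome <- simulate_genome(cfg, reference)
  res <- with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    frags <- sample_read_pairs(genome, cfg)
    need_seq <- isTRUE(write_fastq)
    fq <- if (need_seq) fragment_sequences(frags, genome, cfg) else NULL
    aln <- emulate_alignment(frags, genome, cfg, include_seq = need_seq,
                             sequences = fq)
    list(frags = frags, aln = aln, fq = fq)
  })
  paths <- list()
  if (!is.null(out_prefix)) {
    paths$vcf <- paste0(out_prefix, ".truth.vcf")
    write_sv_vcf(genome$truth, paths$vcf, contig_length = length(genome$reference))
    paths$sam <- paste0(out_prefix, ".sam")
    write_sam(res$aln, paths$sam, cfg$chrom, length(genome$reference))
    if (write_bam)
      paths$bam <- Rsamtools::asBam(paths$sam, destination = out_prefix,
                                    overwrite = TRUE, indexDestination = FALSE)
    if (write_fastq) {
      paths$fastq <- write_fastq_pair(res$frags$qname, res$fq$seq1, res$fq$seq2,
                                      out_prefix)
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      paths$config <- paste0(out_prefix, ".config.json")
      jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                           null = "null")
    }
  }
  out <- list(truth = genome$truth, alignments = res$aln, fragments = res$frags,
              genome = genome, config = cfg, paths = paths)
  class(out) <- "sv_simulation"
  out
}
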