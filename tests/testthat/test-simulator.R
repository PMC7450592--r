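test_that("null planting leaves both haplotypes equal to the reference", {
  cfg <- sim_config(region_length = 5e4,
                    n_calls = c(N = 5, G1 = 0, G2 = 0, G3 = 0, G4 = 0),
                    elevated_snv_rate = 0, background_snv_rate = 0, seed = 1)
  g <- simulate_genome(cfg)
  expect_identical(g$h1$seq, g$reference)
  expect_identical(g$h2$seq, g$reference)
  expect_equal(nrow(g$truth), 5)
  expect_true(all(g$truth$gtclass == "N"))
})

test_that("a G3 call amplifies the variant-bearing segment to copy_number copies", {
  cfg <- sim_config(region_length = 6e4,
                    n_calls = c(N = 0, G1 = 0, G2 = 0, G3 = 1, G4 = 0),
                    copy_number = 3, elevated_snv_rate = 0,
                    background_snv_rate = 0, seed = 3)
  g <- simulate_genome(cfg)
  tr <- g$truth
  hap <- if (tr$hap == 1) g$h1 else g$h2
  wild <- if (tr$hap == 1) g$h2 else g$h1
  # three tandem copies: three blocks on the mutated haplotype start at the
  # CNV segment start; the wild haplotype has no breakpoint there
  expect_equal(sum(hap$map$ref_start == tr$cnv_start, na.rm = TRUE), 3)
  expect_equal(nrow(wild$map), 1)
  # each copy carries the variant: deletion shortens, insertion lengthens
  exp_unit <- switch(tr$sv_type,
    DEL = (tr$cnv_end - tr$cnv_start + 1) - (tr$length + 1),
    INS = (tr$cnv_end - tr$cnv_start + 1) + tr$length,
    INV = tr$cnv_end - tr$cnv_start + 1,
    CPX = tr$cnv_end - tr$cnv_start + 1 - 1)  # del [pos,end], ins of L
  hap_extra <- length(hap$seq) - length(g$reference)
  expect_equal(hap_extra, 3 * exp_unit - (tr$cnv_end - tr$cnv_start + 1))
})

test_that("the default configuration plants the full five-class census", {
  cfg <- sim_config(seed = 5)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$truth), 300)
  expect_equal(as.vector(table(factor(g$truth$gtclass, genotype_classes()))),
               c(60, 80, 80, 50, 30))
  expect_true(all(g$truth$length >= 500 & g$truth$length <= 5000))
  cnv <- g$truth[g$truth$gtclass %in% c("G3", "G4"), ]
  cnv_len <- cnv$cnv_end - cnv$cnv_start
  expect_true(all(cnv_len >= 1000 & cnv_len <= 5000))
  # footprints are disjoint
  spans <- ifelse(is.na(g$truth$cnv_start), g$truth$pos, g$truth$cnv_start)
  ends <- ifelse(is.na(g$truth$cnv_end), g$truth$end, g$truth$cnv_end)
  o <- order(spans)
  expect_true(all(spans[o][-1] > ends[o][-length(ends)]))
})

test_that("SNV planting honours its rates", {
  ref <- rep("A", 10000)
  cfg0 <- sim_config(region_length = 10000, elevated_snv_rate = 0,
                     background_snv_rate = 0)
  s0 <- plant_snvs(ref, NULL, cfg0)
  expect_identical(s0$h1, ref)
  expect_identical(s0$h2, ref)
  # certainty inside a window
  truth <- sv_calls("w", "c1", 5001, 5010, "DEL")
  truth$gtclass <- "G2"
  cfg1 <- sim_config(region_length = 10000, elevated_snv_rate = 1,
                     background_snv_rate = 0, elevated_pad = 0)
  s1 <- plant_snvs(ref, truth, cfg1)
  expect_true(all(s1$h1[5001:5010] != "A"))
  expect_true(all(s1$h1[-(5001:5010)] == "A"))
  # background count is binomial around rate * length
  ref2 <- rep("C", 1e6)
  cfg2 <- sim_config(region_length = 1e6, background_snv_rate = 1e-4)
  set.seed(11)
  s2 <- plant_snvs(ref2, NULL, cfg2)
  expect_lt(abs(s2$n_h1 - 100), 3 * sqrt(100))
  expect_lt(abs(s2$n_h2 - 100), 3 * sqrt(100))
})

test_that("pair counts follow the coverage arithmetic", {
  cfg <- sim_config(region_length = 2e5,
                    n_calls = c(N = 2, G1 = 2, G2 = 2, G3 = 1, G4 = 1),
                    coverage = 10, elevated_snv_rate = 0,
                    background_snv_rate = 0, seed = 8)
  g <- simulate_genome(cfg)
  set.seed(8)
  frags <- sample_read_pairs(g, cfg)
  # coverage * L / (2 * read_length) pairs in total over both haplotypes
  expect_lt(abs(nrow(frags) - 10 * 2e5 / 200) / (10 * 2e5 / 200), 0.05)
  # all inserts respect the redraw bounds
  expect_true(all(frags$insert >= 200))
})

test_that("read sequences match the haplotype exactly at zero error rate", {
  cfg <- sim_config(region_length = 5e4,
                    n_calls = c(N = 1, G1 = 1, G2 = 1, G3 = 1, G4 = 1),
                    coverage = 2, base_error_rate = 0, seed = 12)
  sim <- simulate_sv_data(cfg, write_fastq = TRUE,
                          out_prefix = tempfile())
  fq <- readLines(sim$paths$fastq[1])
  seqs <- fq[seq(2, length(fq), by = 4)]
  hap_str <- vapply(list(sim$genome$reference, sim$genome$h1$seq,
                         sim$genome$h2$seq), paste, "", collapse = "")
  fr <- sim$fragments
  expect_equal(seqs,
               substring(hap_str[fr$hap + 1], fr$start, fr$start + 99))
})

test_that("alignment emulation follows the breakpoint rules", {
  # genome: 10 kbp reference, one 2 kbp deletion at [4001, 6000] on h1
  cfg <- sim_config(region_length = 1e4, elevated_snv_rate = 0,
                    background_snv_rate = 0)
  set.seed(2)
  ref <- sample(c("A", "C", "G", "T"), 1e4, replace = TRUE)
  ev <- list(list(kind = "sv", type = "DEL", pos = 4001L, end = 6000L,
                  svlen = 2000L, insert = NULL))
  h1 <- svgeno:::build_haplotype(ref, ev)
  # read fully left of the breakpoint: full-length match at its own position
  m <- svgeno:::map_reads(1000, 1099, h1$map, 100)
  expect_equal(m$pos, 1000L)
  expect_equal(m$cigar, "100M")
  expect_equal(m$mapq, 60L)
  # read crossing the junction (hap 3951..4050: 50 bp anchor each side)
  m2 <- svgeno:::map_reads(3951, 4050, h1$map, 100)
  expect_equal(m2$mapq, 30L)
  expect_true(m2$cigar %in% c("50M50S", "50S50M"))
  # anchored on the left: POS at the anchor start
  expect_equal(m2$pos, 3951L)
  # read beyond the junction maps past the deleted segment
  m3 <- svgeno:::map_reads(4001, 4100, h1$map, 100)
  expect_equal(m3$pos, 6001L)
  # a pair straddling the deletion shows an inflated template length
  genome <- list(reference = ref, h1 = h1,
                 h2 = list(seq = ref, map = data.frame(
                   hap_start = 1, hap_end = 1e4, ref_start = 1L,
                   ref_end = 1e4L, strand = 1L, novel = FALSE)),
                 truth = NULL, chrom = "sim1")
  frags <- data.frame(qname = "p1", hap = 1, start = 3800L, insert = 500L,
                      swap = FALSE)
  rec <- emulate_alignment(frags, genome, cfg)
  expect_equal(abs(rec$tlen[1]), 2500)
  expect_true(all(bitwAnd(rec$flag, 2L) == 0))  # not a proper pair
})

test_that("reads inside novel insertions are unmapped with an anchored mate", {
  set.seed(4)
  ref <- sample(c("A", "C", "G", "T"), 1e4, replace = TRUE)
  ins_seq <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  ev <- list(list(kind = "sv", type = "INS", pos = 5001L, end = 8001L,
                  svlen = 3000L, insert = list(nearby = FALSE, seq = ins_seq)))
  h1 <- svgeno:::build_haplotype(ref, ev)
  # read wholly inside the novel insert (hap coords 5001..8000 are novel)
  m <- svgeno:::map_reads(6000, 6099, h1$map, 100)
  expect_false(m$mapped)
  # 50 bp in the insert, 50 bp reference anchor -> clipped at MAPQ 30
  m2 <- svgeno:::map_reads(4951, 5050, h1$map, 100)
  expect_equal(m2$mapq, 30L)
  expect_true(m2$cigar %in% c("50M50S", "50S50M"))
})

test_that("inverted segments map reverse-complemented at mirrored positions", {
  set.seed(6)
  ref <- sample(c("A", "C", "G", "T"), 1e4, replace = TRUE)
  ev <- list(list(kind = "sv", type = "INV", pos = 3001L, end = 5000L,
                  svlen = 1999L, insert = NULL))
  h1 <- svgeno:::build_haplotype(ref, ev)
  expect_equal(length(h1$seq), 1e4)
  m <- svgeno:::map_reads(3001, 3100, h1$map, 100)
  expect_true(m$mapped)
  expect_true(m$flip)
  # first 100 bases of the inversion come from its far end
  expect_equal(m$pos, 4901L)
  expect_equal(paste(h1$seq[3001:3100], collapse = ""),
               paste(chartr("ACGT", "TGCA", rev(ref[4901:5000])), collapse = ""))
})

test_that("identical seeds give byte-identical outputs, different seeds differ", {
  cfg <- sim_config(region_length = 6e4,
                    n_calls = c(N = 2, G1 = 2, G2 = 2, G3 = 2, G4 = 2),
                    coverage = 4, seed = 31)
  p1 <- tempfile(); p2 <- tempfile()
  simulate_sv_data(cfg, out_prefix = p1, write_fastq = TRUE)
  simulate_sv_data(cfg, out_prefix = p2, write_fastq = TRUE)
  expect_identical(readLines(paste0(p1, ".sam")), readLines(paste0(p2, ".sam")))
  expect_identical(readLines(paste0(p1, ".truth.vcf")),
                   readLines(paste0(p2, ".truth.vcf")))
  expect_identical(readLines(paste0(p1, "_1.fastq")),
                   readLines(paste0(p2, "_1.fastq")))
  cfg2 <- cfg; cfg2$seed <- 32
  p3 <- tempfile()
  simulate_sv_data(cfg2, out_prefix = p3, write_fastq = TRUE)
  expect_false(identical(readLines(paste0(p1, ".sam")),
                         readLines(paste0(p3, ".sam"))))
})

test_that("realized depth in CNV-free regions is within 10% of the target", {
  sim <- small_sim()   # coverage 10
  truth <- sim$truth
  # windows far from every footprint: use the N-call cores
  ncalls <- truth[truth$gtclass == "N", ]
  aln <- sim$alignments
  depths <- vapply(seq_len(nrow(ncalls)), function(i) {
    s <- ncalls$pos[i]; e <- ncalls$end[i]
    sum(!aln$unmapped & aln$pos >= s & aln$pos <= e) * 100 / (e - s + 1)
  }, numeric(1))
  expect_lt(abs(mean(depths) - 10) / 10, 0.1)
})
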