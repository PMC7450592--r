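make_pairs <- function(inserts, in1 = TRUE, in2 = TRUE) {
  n <- length(inserts)
  r <- function(x) rep_len(x, n)
  data.frame(qname = if (n) paste0("q", seq_len(n)) else character(0),
             pos1 = r(1), cigar1 = r("100M"), mapq1 = r(60), flag1 = r(99),
             mapped1 = r(TRUE),
             pos2 = r(1), cigar2 = r("100M"), mapq2 = r(60), flag2 = r(147),
             mapped2 = r(TRUE),
             insert_size = inserts, in1 = r(in1), in2 = r(in2),
             stringsAsFactors = FALSE)
}

test_that("insert-size concordance is inclusive at mu +/- 3 sigma", {
  s <- insert_stats(500, 15)
  f <- count_insert_size_features(make_pairs(c(500, 545, 546)), s)
  expect_equal(f[["normal_read"]], 2)   # 545 = mu + 3 sigma counts as normal
  expect_equal(f[["abnormal_read"]], 1)
  f2 <- count_insert_size_features(make_pairs(c(455, 454)), s)
  expect_equal(f2[["normal_read"]], 1)
  # empty region
  f3 <- count_insert_size_features(make_pairs(numeric(0)), s)
  expect_equal(unname(f3), c(0, 0))
  # a pair with an unmapped mate counts in neither bucket
  p <- make_pairs(c(500, 700))
  p$mapped2[2] <- FALSE
  f4 <- count_insert_size_features(p, s)
  expect_equal(unname(f4), c(1, 0))
})

test_that("CIGAR categories follow the full-match token rules", {
  recs <- data.frame(
    qname = c("a", "a", "b", "b"),
    flag = c(99, 147, 99, 147),
    pos = c(100, 150, 120, 170),
    mapq = 60, cigar = c("100M", "100M", "100M", "60M40S"),
    unmapped = FALSE, stringsAsFactors = FALSE)
  pairs <- data.frame(
    qname = c("a", "b"),
    pos1 = c(100, 120), cigar1 = c("100M", "100M"), mapq1 = 60,
    flag1 = c(99, 99), mapped1 = TRUE,
    pos2 = c(150, 170), cigar2 = c("100M", "60M40S"), mapq2 = 60,
    flag2 = c(147, 147), mapped2 = TRUE,
    insert_size = c(500, 500), in1 = TRUE, in2 = TRUE,
    stringsAsFactors = FALSE)
  f <- count_alignment_features(recs, pairs, 100)
  # pair a: both full -> fully_mapped; pair b: one full + one clipped ->
  # the full mate is single_mapped and the clipped one incompletely_mapped
  expect_equal(f[["fully_mapped"]], 1)
  expect_equal(f[["single_mapped"]], 1)
  expect_equal(f[["incompletely_mapped"]], 1)
  expect_equal(f[["split_mapped"]], 0)
  # empty input
  f0 <- count_alignment_features(recs[0, ], pairs[0, ], 100)
  expect_true(all(f0 == 0))
})

test_that("direction features use exact FLAG equality", {
  recs <- data.frame(flag = c(83, 83, 163, 99))
  expect_equal(unname(count_direction_features(recs)), c(2, 1))
  # a compound flag (83 + secondary bit) does not count
  expect_equal(unname(count_direction_features(data.frame(flag = 339))), c(0, 0))
})

test_that("depth features implement the weighted-depth formulas", {
  recs <- data.frame(mapq = c(60, 30, 60, 15), unmapped = FALSE)
  expect_equal(sum_mapping_qualities(recs), 165)
  expect_equal(sum_mapping_qualities(recs[0, ]), 0)
  expect_equal(read_depth(data.frame(mapq = rep(0, 20), unmapped = FALSE), 2000),
               0.01)
  # sum(Q_i / Q_max) / L with the hand-computed weight sum 2.75
  expect_equal(weighted_read_depth(recs, 1000, 60), 2.75 / 1000)
  # all reads at Q_max: weights collapse to 1 and W_RD = D
  r2 <- data.frame(mapq = rep(60, 7), unmapped = FALSE)
  expect_equal(weighted_read_depth(r2, 350, 60), read_depth(r2, 350))
  # empty region
  expect_equal(weighted_read_depth(recs[0, ], 100, 60), 0)
  # L = 0 falls back to the supplied core width
  expect_equal(read_depth(r2, 0, fallback_width = 700), 0.01)
  expect_error(read_depth(r2, 0), "fallback")
})

test_that("affected reads count POS membership in the vicinity", {
  aln <- data.frame(pos = c(90, 100, 150, 200, 201), unmapped = FALSE)
  expect_equal(count_affected_reads(aln, 100, 200), 3)
  expect_equal(count_affected_reads(aln[0, ], 100, 200), 0)
})

test_that("all fifteen features agree with the text-scan oracle on fixtures", {
  path <- write_sam_fixture(mixed_fixture_lines())
  aln <- read_alignments(path)
  stats <- insert_stats(500, 15)
  cases <- list(c(1100, 1500), c(950, 1050), c(2000, 2900))
  for (ce in cases) {
    call <- sv_calls("x", "sim1", ce[1], ce[2], "DEL")
    feat <- extract_features(call, aln, stats = stats, read_length = 100,
                             reference_length = 1e5)
    want <- oracle_features(path, ce[1], ce[2], 500, 15, 100, 1e5)
    got <- unlist(feat[1, feature_names()])
    expect_equal(got, want[feature_names()], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("features agree with the text-scan oracle on simulated alignments", {
  sim <- small_sim()
  path <- tempfile(fileext = ".sam")
  write_sam(sim$alignments, path, "sim1", sim$config$region_length)
  aln <- read_alignments(path)
  stats <- insert_stats(500, 15)
  idx <- c(3, 40, 77, 110)   # a few calls across the classes
  for (i in idx) {
    call <- sim$truth[i, ]
    feat <- extract_features(call, aln, stats = stats, read_length = 100,
                             reference_length = sim$config$region_length)
    want <- oracle_features(path, call$pos, call$end, 500, 15, 100,
                            sim$config$region_length)
    expect_equal(unlist(feat[1, feature_names()]), want[feature_names()],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("weighted depth never exceeds depth; extended covers core", {
  sim <- small_sim()
  feat <- extract_features(sim$truth, sim$alignments,
                           stats = insert_stats(500, 15),
                           reference_length = sim$config$region_length)
  expect_true(all(feat$weighted_read_depth <= feat$read_depth + 1e-12))
  expect_true(all(feat$ext_weighted_read_depth >= feat$weighted_read_depth - 1e-12))
  expect_true(all(feat$variant_length == sim$truth$length))
  counts <- as.matrix(feat[, c("abnormal_read", "normal_read",
                               "incompletely_mapped", "fully_mapped",
                               "split_mapped", "single_mapped", "unmapped",
                               "affected_reads", "direction1", "direction2")])
  expect_true(all(counts >= 0 & counts == round(counts)))
})

test_that("feature extraction is deterministic and TSV round-trips", {
  sim <- small_sim()
  s <- insert_stats(500, 15)
  f1 <- extract_features(sim$truth[1:10, ], sim$alignments, stats = s)
  f2 <- extract_features(sim$truth[1:10, ], sim$alignments, stats = s)
  expect_identical(f1, f2)
  path <- tempfile(fileext = ".tsv")
  write_features(f1, path)
  back <- read_features(path)
  expect_equal(back$call_id, f1$call_id)
  expect_equal(as.matrix(back[, feature_names()]),
               as.matrix(f1[, feature_names()]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("an empty region yields zero counts with the length preserved", {
  sim <- small_sim()
  far <- sv_calls("far", "sim1", 449000, 449800, "DEL")
  aln <- sim$alignments[sim$alignments$pos < 400000, ]
  feat <- extract_features(far, aln, stats = insert_stats(500, 15),
                           reference_length = 4.5e5)
  expect_equal(feat$variant_length, 800)
  expect_true(all(unlist(feat[, setdiff(feature_names(), "variant_length")]) == 0))
})
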