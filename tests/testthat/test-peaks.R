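si1 <- mbdpipe:::make_seqinfo(c(chr1 = 1e6))

test_that("deduplication keeps one read per position and is idempotent", {
  # five identical reads collapse to one
  dup <- gr0("chr1", rep(100, 5), rep(300, 5), seqinfo = si1,
             strand = rep("+", 5))
  expect_equal(length(deduplicate_reads(dup)), 1)

  # all-distinct input passes through
  distinct <- gr0("chr1", c(0, 500, 1000), c(200, 700, 1200), seqinfo = si1,
                  strand = c("+", "-", "+"))
  expect_equal(length(deduplicate_reads(distinct)), 3)

  # random multiset vs brute-force unique-key oracle
  set.seed(42)
  n <- 10000
  s <- sample.int(5000, n, replace = TRUE)
  str <- sample(c("+", "-"), n, replace = TRUE)
  reads <- gr0("chr1", s, s + 200, seqinfo = si1, strand = str)
  dd <- deduplicate_reads(reads)
  expect_equal(length(dd), length(unique(paste(s, str))))
  # idempotence and order-independence
  expect_identical(as.data.frame(deduplicate_reads(dd)), as.data.frame(dd))
  shuf <- reads[sample(n)]
  expect_identical(as.data.frame(deduplicate_reads(shuf)),
                   as.data.frame(dd))

  # strand can be excluded from the key (stricter collapse)
  two <- gr0("chr1", c(100, 100), c(300, 300), seqinfo = si1,
             strand = c("+", "-"))
  expect_equal(length(deduplicate_reads(two)), 2)
  expect_equal(length(deduplicate_reads(two, by_strand = FALSE)), 1)
})

test_that("coverage counts are conserved and placed by fragment midpoint", {
  r <- gr0("chr1", 200, 400, seqinfo = si1) # aligned to a bin boundary
  cov <- compute_coverage(r, si1, bin_size = 200)
  expect_equal(sum(cov$counts$chr1), 1)
  expect_equal(which(cov$counts$chr1 == 1), 2) # midpoint 300 -> second bin

  set.seed(7)
  s <- sample.int(9e5, 5000)
  cov2 <- compute_coverage(gr0("chr1", s, s + 200, seqinfo = si1), si1, 1000)
  expect_equal(coverage_total(cov2), 5000)

  empty <- compute_coverage(GRanges(seqinfo = si1), si1, 200)
  expect_true(all(empty$counts$chr1 == 0))
  expect_equal(length(empty$counts$chr1), 5000)
})

test_that("reads beyond the chromosome end are rejected by name", {
  bad <- GRanges("chr1", IRanges(999950, 1000150))
  expect_error(compute_coverage(bad, si1, 200), "chr1:999949-1000150")
})

test_that("uniform reads give Poisson-dispersed bin counts", {
  # oracle: uniform placement -> per-bin counts ~ Poisson(n * bin / L);
  # index of dispersion (n-1)s^2/mean ~ chi-square(n-1)
  set.seed(123)
  n <- 20000
  s <- floor(runif(n, 0, 1e6 - 200))
  cov <- compute_coverage(gr0("chr1", s, s + 200, seqinfo = si1), si1, 1000)
  x <- cov$counts$chr1[2:999] # interior bins (edge bins truncated)
  disp <- (length(x) - 1) * var(x) / mean(x)
  expect_gt(disp, qchisq(0.005, length(x) - 1))
  expect_lt(disp, qchisq(0.995, length(x) - 1))
})

test_that("no peaks are called when captured equals background", {
  set.seed(9)
  counts <- rpois(5000, 2)
  track <- structure(list(bin_size = 200L, seqinfo = si1,
                          counts = list(chr1 = counts)),
                     class = "coverage_track_set")
  expect_equal(length(call_peaks(track, track, p_threshold = 1e-5)), 0)
})

test_that("a planted enriched region yields exactly one covering peak", {
  g <- build_genome(c(chr1 = 1e6), 5, 5, seed = 2)
  land <- make_landscape(gr0("chr1", 450000, 451000, seqinfo = g$seqinfo))
  cfg <- lineage_config(depth = 1e5, base_rate = 0.05, enrichment = 20,
                        seed = 13)
  reads <- simulate_mbd_library(land, g, cfg)
  peaks <- call_sample_peaks(reads, g$seqinfo)
  expect_equal(length(peaks), 1)
  expect_true(overlapsAny(gr0("chr1", 450000, 451000, seqinfo = g$seqinfo),
                          peaks))
  expect_true(all(mcols(peaks)$score >= 5)) # every peak passes 1e-5
  expect_true(all(mcols(peaks)$fold_enrichment > 1))
})

test_that("loosening the threshold never uncovers previously called peaks", {
  g <- build_genome(c(chr1 = 1e6), 5, 5, seed = 2)
  land <- make_landscape(gr0("chr1", c(2e5, 6e5), c(2e5 + 1500, 6e5 + 1500),
                             seqinfo = g$seqinfo))
  cfg <- lineage_config(depth = 1e5, base_rate = 0.02, seed = 19)
  reads <- simulate_mbd_library(land, g, cfg)
  fr <- split_fractions(deduplicate_reads(reads))
  cap <- compute_coverage(fr$captured, g$seqinfo, 200)
  bg <- compute_coverage(fr$supernatant, g$seqinfo, 200)
  thresholds <- c(1e-8, 1e-5, 1e-3)
  calls <- lapply(thresholds, function(p) call_peaks(cap, bg,
                                                     p_threshold = p))
  for (i in seq_len(length(calls) - 1)) {
    # every peak at the stricter threshold is covered at the looser one
    if (length(calls[[i]]))
      expect_true(all(overlapsAny(calls[[i]], calls[[i + 1]])))
    expect_lte(length(calls[[i]]), length(calls[[i + 1]]) +
                 sum(countOverlaps(calls[[i + 1]], calls[[i]]) > 1))
  }
})

test_that("empty tracks produce an empty peak list with a warning", {
  zero <- compute_coverage(GRanges(seqinfo = si1), si1, 200)
  expect_warning(pk <- call_peaks(zero, zero), "empty")
  expect_equal(length(pk), 0)
})

test_that("peak BED6+2 round-trips and rejects malformed lines", {
  pk <- make_peaks("chr1", c(1000, 5000), c(2000, 6000), seqinfo = si1)
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, path)
  back <- read_peaks_bed(path, si1)
  expect_equal(start(back), start(pk))
  expect_equal(mcols(back)$n_reads, mcols(pk)$n_reads)
  writeLines(c("chr1\t1\t2"), path)
  expect_error(read_peaks_bed(path, si1), "line 1")
})
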