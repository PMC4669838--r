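# hand-built two-gene genome: one plus-strand coding gene with two exons,
# one minus-strand coding single-exon gene, plus one CGI
toy_genome <- function() {
  si <- mbdpipe:::make_seqinfo(c(chr1 = 100000))
  genes <- data.frame(
    gene_name = c("geneA", "geneB"), tx_name = c("txA", "txB"),
    chrom = "chr1", strand = c("+", "-"),
    tx_start = c(10000L, 60000L), tx_end = c(20000L, 70000L),
    cds_start = c(11000L, 61000L), cds_end = c(19000L, 69000L),
    stringsAsFactors = FALSE)
  genes$exon_starts <- list(c(10000L, 15000L), 60000L)
  genes$exon_ends <- list(c(12000L, 20000L), 70000L)
  cgis <- gr0("chr1", 9500, 10500, seqinfo = si)
  structure(list(seqinfo = si, genes = genes, cgis = cgis),
            class = "annotated_genome")
}

test_that("promoter windows are strand-aware and clipped", {
  fm <- build_feature_map(toy_genome(), promoter_def = c(2000, 500))
  prom <- fm$features$promoter
  pa <- prom[mcols(prom)$gene == "geneA"]
  expect_equal(start(pa) - 1L, 10000 - 2000) # [TSS-2000, TSS+500)
  expect_equal(end(pa), 10000 + 500)
  pb <- prom[mcols(prom)$gene == "geneB"] # minus strand: TSS at tx_end
  expect_equal(start(pb) - 1L, 70000 - 500)
  expect_equal(end(pb), 70000 + 2000)
})

test_that("UTRs derive from CDS vs transcript bounds, introns from exon gaps", {
  fm <- build_feature_map(toy_genome())
  u5 <- fm$features$utr5; u3 <- fm$features$utr3
  # geneA (+): 5' UTR [10000,11000) in exon 1; 3' UTR [19000,20000) in exon 2
  a5 <- u5[mcols(u5)$gene == "geneA"]
  expect_equal(c(start(a5) - 1L, end(a5)), c(10000, 11000))
  a3 <- u3[mcols(u3)$gene == "geneA"]
  expect_equal(c(start(a3) - 1L, end(a3)), c(19000, 20000))
  # geneB (-): 5' UTR at the right transcript end
  b5 <- u5[mcols(u5)$gene == "geneB"]
  expect_equal(c(start(b5) - 1L, end(b5)), c(69000, 70000))
  # single intron of geneA: [12000, 15000)
  intr <- fm$features$intron
  expect_equal(c(start(intr) - 1L, end(intr)), c(12000, 15000))
  # single-exon geneB has no intron bp
  expect_equal(sum(mcols(intr)$gene == "geneB"), 0)
})

test_that("non-coding genes emit no UTRs and are logged", {
  g <- toy_genome()
  g$genes$cds_start[2] <- g$genes$tx_start[2] # geneB becomes non-coding
  g$genes$cds_end[2] <- g$genes$tx_start[2]
  expect_message(fm <- build_feature_map(g), "non-coding")
  expect_equal(sum(mcols(fm$features$utr5)$gene == "geneB"), 0)
  expect_equal(sum(mcols(fm$features$utr3)$gene == "geneB"), 0)
})

test_that("precedence resolves multi-context peaks; intergenic is the fallback", {
  fm <- build_feature_map(toy_genome())
  peaks <- gr0("chr1", c(13000, 9900, 40000, 10400), # intron / prom+5utr+exon
               c(13500, 11500, 41000, 10600), seqinfo = fm$seqinfo)
  cls <- classify_context(peaks, fm)
  expect_equal(as.character(cls$primary_context),
               c("intron", "promoter", "intergenic", "promoter"))
  expect_equal(cls$gene[1:2], c("geneA", "geneA"))
  expect_true(is.na(cls$gene[3]))
  expect_equal(cls$cgi_overlap, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("classification matches the exhaustive per-base oracle", {
  g <- tiny_genome()
  fm <- suppressMessages(build_feature_map(g))
  set.seed(12)
  for (chrom in GenomeInfoDb::seqlevels(g$seqinfo)) {
    len <- GenomeInfoDb::seqlengths(g$seqinfo)[[chrom]]
    P <- rand_disjoint(120, len, max_w = 3000)
    peaks <- gr0(chrom, P$start, P$end, seqinfo = g$seqinfo)
    got <- classify_context(peaks, fm)
    want <- oracle_classify(peaks, fm)
    expect_equal(as.character(got$primary_context), want$context)
    expect_equal(got$cgi_overlap, want$cgi)
    # totality: exactly one context per peak
    expect_false(anyNA(got$primary_context))
  }
})

test_that("context distribution reports counts and per-Mb densities", {
  fm <- build_feature_map(toy_genome())
  peaks <- gr0("chr1", c(8500, 9000, 13000), c(8700, 9300, 13500),
               seqinfo = fm$seqinfo)
  d <- context_distribution(peaks, fm)
  expect_equal(sum(d$count), 3)
  expect_equal(d$count[d$context == "promoter"], 2)
  expect_equal(d$count[d$context == "intron"], 1)
  expect_equal(d$density_per_mb[d$context == "promoter"],
               2 / (d$feature_bp[d$context == "promoter"] / 1e6))
  # zero-bp contexts get an undefined density, not zero
  g2 <- toy_genome(); g2$genes <- g2$genes[1, ]
  g2$genes$exon_starts <- list(c(10000L, 15000L))
  g2$genes$exon_ends <- list(c(12000L, 20000L))
  g2$genes$cds_start <- 10000L; g2$genes$cds_end <- 20000L # no UTRs
  fm2 <- build_feature_map(g2)
  d2 <- context_distribution(peaks, fm2)
  expect_true(is.na(d2$density_per_mb[d2$context == "utr5"]))

  # CGI restriction drops non-CGI peaks
  dcgi <- context_distribution(gr0("chr1", c(9900, 13000), c(10100, 13500),
                                   seqinfo = fm$seqinfo),
                               fm, restrict_to_cgi = TRUE)
  expect_equal(sum(dcgi$count), 1)

  empty <- context_distribution(GRanges(seqinfo = fm$seqinfo), fm)
  expect_equal(sum(empty$count), 0)
})

test_that("feature intervals survive a BED round-trip unchanged", {
  g <- tiny_genome()
  fm <- suppressMessages(build_feature_map(g))
  set.seed(3)
  P <- rand_disjoint(60, 3e5 - 5000, max_w = 2500)
  peaks <- gr0("chr1", P$start, P$end, seqinfo = g$seqinfo)
  before <- classify_context(peaks, fm)
  path <- withr::local_tempfile(fileext = ".bed")
  fm2 <- fm
  for (ctx in names(fm$features)) {
    f <- fm$features[[ctx]]
    df <- data.frame(as.character(seqnames(f)), start(f) - 1L, end(f),
                     mcols(f)$gene, 0, ".")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    bed <- read.table(path, sep = "\t")
    fm2$features[[ctx]] <- gr0(bed$V1, bed$V2, bed$V3, seqinfo = g$seqinfo,
                               gene = bed$V4)
  }
  after <- classify_context(peaks, fm2)
  expect_identical(before, after)
})

test_that("mirroring the genome mirrors promoter assignments", {
  g <- toy_genome()
  len <- 100000L
  gm <- g
  gm$genes$strand <- c("-", "+")[match(g$genes$strand, c("+", "-"))]
  gm$genes$tx_start <- len - g$genes$tx_end
  gm$genes$tx_end <- len - g$genes$tx_start
  gm$genes$cds_start <- len - g$genes$cds_end
  gm$genes$cds_end <- len - g$genes$cds_start
  gm$genes$exon_starts <- lapply(g$genes$exon_ends, function(x) rev(len - x))
  gm$genes$exon_ends <- lapply(g$genes$exon_starts, function(x) rev(len - x))
  fm <- build_feature_map(g); fmm <- build_feature_map(gm)
  set.seed(8)
  P <- rand_disjoint(80, len, max_w = 2000)
  peaks <- gr0("chr1", P$start, P$end, seqinfo = g$seqinfo)
  mirrored <- gr0("chr1", rev(len - P$end), rev(len - P$start),
                  seqinfo = g$seqinfo)
  a <- classify_context(peaks, fm)
  b <- classify_context(mirrored, fmm)
  expect_equal(as.character(a$primary_context),
               rev(as.character(b$primary_context)))
})

test_that("promoter methylation status reflects the DMR partition", {
  fm <- build_feature_map(toy_genome())
  # control-unique peak on geneA promoter; dex-unique on geneB promoter
  unique_a <- make_peaks("chr1", 9700, 10200)
  unique_b <- make_peaks("chr1", 69800, 70500)
  part <- structure(list(unique_a = unique_a, unique_b = unique_b,
                         common = GRanges(), labels = c("control", "dex"),
                         counts = c()), class = "dmr_partition")
  st <- promoter_methylation_status(part, fm)
  expect_equal(st$status[st$gene == "geneA"], "hypomethylated_in_dex")
  expect_equal(st$status[st$gene == "geneB"], "hypermethylated_in_dex")

  # no peaks at all -> unchanged
  none <- structure(list(unique_a = GRanges(), unique_b = GRanges(),
                         common = GRanges(), labels = c("control", "dex")),
                    class = "dmr_partition")
  expect_true(all(promoter_methylation_status(none, fm)$status ==
                    "unchanged"))

  # promoter hit by unique peaks of both conditions -> mixed
  both <- structure(list(unique_a = make_peaks("chr1", 9700, 9900),
                         unique_b = make_peaks("chr1", 10100, 10300),
                         common = GRanges(), labels = c("control", "dex")),
                    class = "dmr_partition")
  expect_message(stm <- promoter_methylation_status(both, fm), "mixed")
  expect_equal(stm$status[stm$gene == "geneA"], "mixed")
})
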