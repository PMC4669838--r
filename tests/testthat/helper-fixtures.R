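suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# GRanges builder from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, seqinfo = NULL, ...) {
  g <- GRanges(chrom, IRanges(start0 + 1, end0), ...)
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqlevels(seqinfo)
    seqinfo(g) <- seqinfo
  }
  g
}

# peak-shaped GRanges (mcols required by the BED6+2 writer)
make_peaks <- function(chrom, start0, end0, seqinfo = NULL) {
  g <- gr0(chrom, start0, end0, seqinfo)
  mcols(g) <- DataFrame(score = rep(10, length(g)),
                        fold_enrichment = rep(5, length(g)),
                        n_reads = rep(10L, length(g)))
  g
}

# random internally-disjoint peak set on one chromosome (0-based coords)
rand_disjoint <- function(n, len, max_w = 2000, min_w = 50) {
  s <- sort(sample.int(len - max_w, n))
  w <- sample(min_w:max_w, n, replace = TRUE)
  e <- pmin(s + w, len)
  # greedy scan to guarantee disjointness
  keep <- logical(n); last <- -1
  for (i in seq_len(n)) if (s[i] > last) { keep[i] <- TRUE; last <- e[i] }
  list(start = s[keep], end = e[keep])
}

# hand-made methylation landscape around a plain GRanges of methylated regions
make_landscape <- function(regions, sample_id = "s", condition = "control",
                           stage = "P1", level = 1) {
  mcols(regions) <- DataFrame(
    region_id = sprintf("r%03d", seq_along(regions)),
    methylated = rep(TRUE, length(regions)),
    level = rep(level, length.out = length(regions)),
    origin = rep("placed", length(regions)))
  structure(list(sample_id = sample_id, condition = condition, stage = stage,
                 regions = regions), class = "methylation_landscape")
}

# small annotated genome shared by annotation tests
tiny_genome <- function(seed = 11, chrom_sizes = c(chr1 = 3e5, chr2 = 2e5),
                        n_genes = 20, n_cgis = 15) {
  build_genome(chrom_sizes, n_genes = n_genes, n_cgis = n_cgis, seed = seed,
               gene_length_range = c(2000, 8000))
}
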