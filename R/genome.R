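#' Build a synthetic annotated genome
#'
#' Constructs the coordinate universe for a simulation run: a small
#' multi-chromosome genome carrying non-overlapping gene models (refFlat
#' semantics: transcript span, CDS bounds, sorted non-overlapping exon
#' blocks) and CpG islands, a configurable fraction of which sit on a
#' transcription start site so that promoter/CGI overlap — the hallmark of
#' mammalian promoters — is represented.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param n_genes Number of gene models to place.
#' @param n_cgis Number of CpG islands to place.
#' @param seed Integer seed; the whole genome is deterministic given it.
#' @param promoter_cgi_frac Fraction of CGIs centred on a TSS (default 0.5).
#' @param gene_length_range Transcript length range in bp.
#' @param max_exons Maximum exons per transcript.
#' @param cgi_width_range CGI width range in bp.
#' @param coding_frac Fraction of genes given a CDS; the rest are non-coding
#'   (`cds_start == cds_end`, refFlat convention).
#' @return An object of class `annotated_genome`: list with `seqinfo`
#'   (`Seqinfo`), `genes` (refFlat-style data frame, 0-based half-open) and
#'   `cgis` (`GRanges`).
#' @export
#' @examples
#' g <- build_genome(c(chr1 = 1e6), n_genes = 50, n_cgis = 30, seed = 7)
#' nrow(g$genes)
build_genome <- function(chrom_sizes, n_genes, n_cgis, seed,
                         promoter_cgi_frac = 0.5,
                         gene_length_range = c(2000, 20000),
                         max_exons = 8,
                         cgi_width_range = c(300, 2000),
                         coding_frac = 0.8) {
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  assert_positive(n_genes, "n_genes"); assert_positive(n_cgis, "n_cgis")
  assert_probability(promoter_cgi_frac, "promoter_cgi_frac")
  si <- make_seqinfo(chrom_sizes)
  set.seed(derive_seed(seed, "genome"))

  lens <- as.numeric(GenomeInfoDb::seqlengths(si))
  chroms <- GenomeInfoDb::seqlevels(si)
  gene_len <- sample(gene_length_range[1]:gene_length_range[2],
                     n_genes, replace = TRUE)
  placed <- place_intervals(si, gene_len)

  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  coding <- runif(n_genes) < coding_frac
  genes <- data.frame(
    gene_name = sprintf("gene%04d", seq_len(n_genes)),
    tx_name = sprintf("tx%04d", seq_len(n_genes)),
    chrom = as.character(seqnames(placed)),
    strand = strand,
    tx_start = start(placed) - 1L,
    tx_end = end(placed),
    stringsAsFactors = FALSE)

  exon_blocks <- lapply(seq_len(n_genes), function(i) {
    s <- genes$tx_start[i]; e <- genes$tx_end[i]
    len <- e - s
    k <- sample.int(min(max_exons, max(1L, len %/% 400L)), 1)
    if (k == 1L) return(list(starts = s, ends = e))
    # 2k-2 interior breakpoints -> alternating exon/intron, exons at both ends
    bp <- sort(sample((s + 1):(e - 1), 2L * k - 2L))
    starts <- c(s, bp[seq(2, length(bp), by = 2)])
    ends <- c(bp[seq(1, length(bp), by = 2)], e)
    list(starts = as.integer(starts), ends = as.integer(ends))
  })
  genes$exon_starts <- lapply(exon_blocks, `[[`, "starts")
  genes$exon_ends <- lapply(exon_blocks, `[[`, "ends")

  # CDS inset ~10% from each transcript end; non-coding: cdsStart == cdsEnd
  inset <- pmax(1L, as.integer(0.1 * (genes$tx_end - genes$tx_start)))
  genes$cds_start <- ifelse(coding, genes$tx_start + inset, genes$tx_start)
  genes$cds_end <- ifelse(coding, genes$tx_end - inset, genes$tx_start)

  # CGIs: a fraction centred on a TSS, the rest uniform; mutually non-overlapping
  cgi_w <- sample(cgi_width_range[1]:cgi_width_range[2], n_cgis, replace = TRUE)
  n_prom <- round(promoter_cgi_frac * n_cgis)
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  offs <- cumsum(c(0, lens))
  kept_s <- kept_e <- numeric(0)
  cgi_chrom <- integer(n_cgis); cgi_start <- numeric(n_cgis)
  for (i in seq_len(n_cgis)) {
    w <- cgi_w[i]
    ok <- FALSE
    for (try in 1:1000) {
      if (i <= n_prom && n_genes > 0) {
        gi <- sample.int(n_genes, 1)
        ci <- match(genes$chrom[gi], chroms)
        s0 <- tss[gi] - w %/% 2L
      } else {
        ci <- sample.int(length(chroms), 1, prob = lens)
        s0 <- floor(runif(1, 0, max(1, lens[ci] - w)))
      }
      s0 <- max(0, min(s0, lens[ci] - w))
      gs <- offs[ci] + s0; ge <- gs + w
      p <- findInterval(gs, kept_s)
      clash <- (p > 0 && kept_e[p] > gs) ||
        (p < length(kept_s) && ge > kept_s[p + 1])
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible packing: could not place CpG island", call. = FALSE)
    p <- findInterval(gs, kept_s)
    kept_s <- append(kept_s, gs, after = p)
    kept_e <- append(kept_e, ge, after = p)
    cgi_chrom[i] <- ci; cgi_start[i] <- s0
  }
  cgis <- GRanges(chroms[cgi_chrom],
                  IRanges(cgi_start + 1, cgi_start + cgi_w), seqinfo = si)

  genome <- structure(list(seqinfo = si, genes = genes, cgis = sort(cgis)),
                      class = "annotated_genome")
  validate_genome(genome)
  genome
}

#' Validate an annotated genome
#'
#' Checks the structural invariants: positive chromosome lengths, all gene
#' and CGI intervals within their chromosome, exon blocks sorted,
#' non-overlapping and spanning the transcript, CDS inside the transcript.
#'
#' @param genome `annotated_genome`.
#' @return `genome`, invisibly; errors on violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  si <- genome$seqinfo
  if (any(GenomeInfoDb::seqlengths(si) <= 0))
    stop("chromosome lengths must be > 0")
  validate_genes(genome$genes)
  lens <- GenomeInfoDb::seqlengths(si)[genome$genes$chrom]
  if (any(genome$genes$tx_end > lens))
    stop("gene extends beyond its chromosome")
  if (length(genome$cgis) &&
      any(end(genome$cgis) >
          GenomeInfoDb::seqlengths(si)[as.character(seqnames(genome$cgis))]))
    stop("CGI extends beyond its chromosome")
  invisible(genome)
}

# refFlat-level gene invariants, shared by the builder and the reader
validate_genes <- function(genes) {
  stopifnot(all(c("gene_name", "chrom", "strand", "tx_start", "tx_end",
                  "cds_start", "cds_end", "exon_starts", "exon_ends") %in%
                  names(genes)))
  if (any(genes$tx_start >= genes$tx_end)) stop("tx_start must be < tx_end")
  if (any(genes$cds_start < genes$tx_start | genes$cds_end > genes$tx_end |
            genes$cds_start > genes$cds_end))
    stop("CDS bounds must lie within the transcript")
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) < 1L) stop("every gene needs at least one exon")
    if (length(es) != length(ee) || any(es >= ee))
      stop("exon blocks malformed")
    if (is.unsorted(es, strictly = TRUE) ||
        any(ee[-length(ee)] > es[-1]))
      stop("exon blocks must be sorted and non-overlapping")
    if (es[1] < genes$tx_start[i] || ee[length(ee)] > genes$tx_end[i])
      stop("exon blocks must lie within the transcript span")
  }
  invisible(genes)
}

#' Transcript spans of an annotated genome as GRanges
#' @param genome `annotated_genome`.
#' @return `GRanges` with mcols `gene` and strand set.
#' @export
gene_granges <- function(genome) {
  g <- genome$genes
  GRanges(g$chrom, IRanges(g$tx_start + 1L, g$tx_end), strand = g$strand,
          gene = g$gene_name, seqinfo = genome$seqinfo)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d chromosome(s), %.2f Mb, %d genes, %d CGIs\n",
              length(GenomeInfoDb::seqlevels(x$seqinfo)),
              sum(as.numeric(GenomeInfoDb::seqlengths(x$seqinfo))) / 1e6,
              nrow(x$genes), length(x$cgis)))
  invisible(x)
}
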