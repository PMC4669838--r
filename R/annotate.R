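#' Build per-context feature intervals from gene models
#'
#' Derives the classic genomic contexts from refFlat-style gene models:
#' strand-aware promoter windows around each TSS, 5' and 3' UTRs (exonic
#' sequence between the transcript and CDS bounds; non-coding transcripts,
#' where `cds_start == cds_end`, contribute none), exons, and introns
#' (transcript minus exons). Each context carries its total non-redundant
#' bp, the denominator for gene-model-normalized peak densities.
#'
#' @param genome `annotated_genome`.
#' @param promoter_def Numeric pair: bp upstream and downstream of the TSS
#'   (default `c(2000, 500)`).
#' @return Object of class `feature_map`: list with `features` (named list
#'   of `GRanges` with mcols `gene`: promoter, utr5, utr3, exon, intron),
#'   `feature_bp` (named vector incl. `intergenic`), `cgis`, `seqinfo`,
#'   `promoter_def`.
#' @export
build_feature_map <- function(genome, promoter_def = c(2000, 500)) {
  stopifnot(inherits(genome, "annotated_genome"),
            length(promoter_def) == 2L, all(promoter_def >= 0))
  si <- genome$seqinfo
  g <- genome$genes
  lens <- GenomeInfoDb::seqlengths(si)
  up <- promoter_def[1]; down <- promoter_def[2]

  plus <- g$strand == "+"
  tss <- ifelse(plus, g$tx_start, g$tx_end) # 0-based
  prom_s0 <- ifelse(plus, tss - up, tss - down)
  prom_e0 <- ifelse(plus, tss + down, tss + up)
  prom_s0 <- pmax(0, prom_s0)
  prom_e0 <- pmin(as.numeric(lens[g$chrom]), prom_e0)
  promoter <- GRanges(g$chrom, IRanges(prom_s0 + 1, prom_e0),
                      gene = g$gene_name, seqinfo = si)

  nex <- lengths(g$exon_starts)
  exon <- GRanges(rep(g$chrom, nex),
                  IRanges(unlist(g$exon_starts) + 1, unlist(g$exon_ends)),
                  gene = rep(g$gene_name, nex), seqinfo = si)

  intron_list <- lapply(seq_len(nrow(g)), function(i) {
    ex <- IRanges(g$exon_starts[[i]] + 1, g$exon_ends[[i]])
    IRanges::setdiff(IRanges(g$tx_start[i] + 1, g$tx_end[i]), ex)
  })
  n_int <- lengths(intron_list)
  intron <- GRanges(rep(g$chrom, n_int),
                    unlist(IRanges::IRangesList(intron_list)),
                    gene = rep(g$gene_name, n_int), seqinfo = si)

  coding <- g$cds_start < g$cds_end
  utr_one <- function(left) {
    # left = TRUE: [tx_start, cds_start); FALSE: [cds_end, tx_end)
    idx <- which(coding &
                   (if (left) g$cds_start > g$tx_start
                    else g$cds_end < g$tx_end))
    parts <- lapply(idx, function(i) {
      span <- if (left) IRanges(g$tx_start[i] + 1, g$cds_start[i])
              else IRanges(g$cds_end[i] + 1, g$tx_end[i])
      ex <- IRanges(g$exon_starts[[i]] + 1, g$exon_ends[[i]])
      IRanges::intersect(span, ex)
    })
    np <- lengths(parts)
    GRanges(rep(g$chrom[idx], np),
            unlist(IRanges::IRangesList(parts)),
            gene = rep(g$gene_name[idx], np), seqinfo = si)
  }
  utr_left <- utr_one(TRUE)   # upstream-of-CDS in genome coordinates
  utr_right <- utr_one(FALSE)
  # 5' UTR is the transcript end holding the TSS: left for +, right for -
  left_plus <- g$strand[match(mcols(utr_left)$gene, g$gene_name)] == "+"
  right_plus <- g$strand[match(mcols(utr_right)$gene, g$gene_name)] == "+"
  utr5 <- c(utr_left[left_plus], utr_right[!right_plus])
  utr3 <- c(utr_left[!left_plus], utr_right[right_plus])
  if (any(!coding))
    message(sprintf("%d non-coding transcript(s): no UTRs emitted",
                    sum(!coding)))

  features <- list(promoter = promoter, utr5 = utr5, utr3 = utr3,
                   exon = exon, intron = intron)
  covered <- GenomicRanges::reduce(
    do.call(c, unname(lapply(features, granges))), ignore.strand = TRUE)
  feature_bp <- c(vapply(features, function(x)
    sum(as.numeric(width(GenomicRanges::reduce(granges(x),
                                               ignore.strand = TRUE)))), 0),
    intergenic = sum(as.numeric(lens)) - sum(as.numeric(width(covered))))

  structure(list(features = features, feature_bp = feature_bp,
                 cgis = genome$cgis, seqinfo = si,
                 promoter_def = promoter_def),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat("feature_map (bp per context):\n")
  print(round(x$feature_bp))
  invisible(x)
}

#' Assign each peak a primary genomic context
#'
#' Among the contexts a peak overlaps, the highest-precedence one wins;
#' peaks overlapping no feature are intergenic. Within the winning context
#' the attributed gene is the one with the largest overlap, ties broken by
#' leftmost position then name. CGI overlap is recorded independently of
#' the primary context.
#'
#' @param peaks `GRanges`.
#' @param feature_map From [build_feature_map()].
#' @param precedence Character vector ordering the genic contexts
#'   (default promoter > 5' UTR > 3' UTR > exon > intron).
#' @return Data frame: chrom, start (0-based), end, primary_context,
#'   cgi_overlap, gene.
#' @export
classify_context <- function(peaks, feature_map,
                             precedence = c("promoter", "utr5", "utr3",
                                            "exon", "intron")) {
  stopifnot(inherits(feature_map, "feature_map"),
            all(precedence %in% names(feature_map$features)))
  n <- length(peaks)
  context <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)
  for (ctx in precedence) {
    if (!any(unassigned)) break
    feat <- feature_map$features[[ctx]]
    hits <- findOverlaps(peaks, feat, ignore.strand = TRUE)
    hits <- hits[unassigned[queryHits(hits)]]
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      ranges(peaks)[queryHits(hits)], ranges(feat)[subjectHits(hits)]))
    h <- data.frame(q = queryHits(hits), s = subjectHits(hits), ov = ov)
    h <- h[order(h$q, -h$ov, start(feat)[h$s], mcols(feat)$gene[h$s]), ]
    h <- h[!duplicated(h$q), ]
    context[h$q] <- ctx
    gene[h$q] <- mcols(feat)$gene[h$s]
    unassigned[h$q] <- FALSE
  }
  data.frame(chrom = as.character(seqnames(peaks)),
             start = start(peaks) - 1L, end = end(peaks),
             primary_context = factor(context,
                                      levels = c(precedence, "intergenic")),
             cgi_overlap = overlapsAny(peaks, feature_map$cgis,
                                       ignore.strand = TRUE),
             gene = gene, stringsAsFactors = FALSE)
}

#' Context distribution of a peak set
#'
#' Tabulates primary contexts, optionally restricted to CGI-overlapping
#' peaks, and reports both raw counts and gene-model-normalized densities
#' (peaks per Mb of context); contexts with zero bp get an undefined (NA)
#' density rather than zero.
#'
#' @param peaks `GRanges`.
#' @param feature_map From [build_feature_map()].
#' @param restrict_to_cgi Tabulate only CGI-overlapping peaks
#'   (default FALSE).
#' @param precedence Passed to [classify_context()].
#' @return Data frame: context, count, feature_bp, density_per_mb.
#' @export
context_distribution <- function(peaks, feature_map, restrict_to_cgi = FALSE,
                                 precedence = c("promoter", "utr5", "utr3",
                                                "exon", "intron")) {
  cls <- classify_context(peaks, feature_map, precedence)
  if (restrict_to_cgi) cls <- cls[cls$cgi_overlap, , drop = FALSE]
  lv <- c(precedence, "intergenic")
  count <- as.integer(table(factor(cls$primary_context, levels = lv)))
  bp <- feature_map$feature_bp[lv]
  density <- ifelse(bp > 0, count / (bp / 1e6), NA_real_)
  data.frame(context = lv, count = count, feature_bp = as.numeric(bp),
             density_per_mb = density, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Promoter methylation status of genes between two conditions
#'
#' Reads a [partition_peaks()] result as a per-gene promoter call: a
#' promoter overlapping a peak unique to the reference condition (a) lost
#' that peak in the treated condition (b), i.e. is hypomethylated in b; a
#' promoter overlapping only a b-unique peak is hypermethylated in b;
#' promoters overlapping both unique sets are flagged mixed; all others
#' are unchanged.
#'
#' @param partition `dmr_partition` with `labels = c(reference, treated)`.
#' @param feature_map From [build_feature_map()].
#' @param genes Optional character vector restricting the report.
#' @return Data frame with columns `gene`, `status`; status values are
#'   `hypomethylated_in_<b>`, `hypermethylated_in_<b>`, `mixed`,
#'   `unchanged`.
#' @export
promoter_methylation_status <- function(partition, feature_map,
                                        genes = NULL) {
  stopifnot(inherits(partition, "dmr_partition"),
            inherits(feature_map, "feature_map"))
  prom <- feature_map$features$promoter
  if (!is.null(genes)) prom <- prom[mcols(prom)$gene %in% genes]
  in_a <- overlapsAny(prom, partition$unique_a, ignore.strand = TRUE)
  in_b <- overlapsAny(prom, partition$unique_b, ignore.strand = TRUE)
  b <- partition$labels[2]
  status <- ifelse(in_a & in_b, "mixed",
            ifelse(in_a, sprintf("hypomethylated_in_%s", b),
            ifelse(in_b, sprintf("hypermethylated_in_%s", b), "unchanged")))
  if (any(in_a & in_b))
    message(sprintf("%d promoter(s) overlap unique peaks of both conditions: status 'mixed'",
                    sum(in_a & in_b)))
  data.frame(gene = mcols(prom)$gene, status = status,
             stringsAsFactors = FALSE)
}
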