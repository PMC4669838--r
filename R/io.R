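#' Read and write pipeline file formats
#'
#' All interval data travel as plain-text UCSC formats: aligned reads as BED6
#' (name = fraction, score = 0), peaks as BED6+2 (extra columns
#' `fold_enrichment` and `n_reads`, strand "."), CpG islands as BED3, gene
#' models as 11-column refFlat, chromosome sizes as a two-column TSV, and
#' qPCR measurements as a five-column TSV. BED/refFlat files are 0-based
#' half-open on disk and become 1-based closed `GRanges` in memory.
#'
#' @name mbdpipe-io
NULL

#' Write aligned reads to BED6
#'
#' @param reads `GRanges` with an mcols column `fraction`
#'   (captured/supernatant).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  stopifnot(is(reads, "GRanges"), "fraction" %in% names(mcols(reads)))
  df <- data.frame(chrom = as.character(seqnames(reads)),
                   start = start(reads) - 1L,
                   end = end(reads),
                   name = as.character(mcols(reads)$fraction),
                   score = rep(0L, length(reads)),
                   strand = as.character(strand(reads)))
  writeLines("# chrom\tstart\tend\tfraction\tscore\tstrand", path)
  write.table(df, path, sep = "\t", quote = FALSE, append = TRUE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned reads from BED6
#'
#' @param path BED6 file whose name column holds the library fraction.
#' @param seqinfo Optional `Seqinfo` used to validate coordinates.
#' @return `GRanges` with mcols column `fraction`.
#' @export
read_reads_bed <- function(path, seqinfo = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  mcols(gr) <- S4Vectors::DataFrame(
    fraction = factor(mcols(gr)$name, levels = c("captured", "supernatant")))
  gr
}

#' Write peaks to BED6+2
#'
#' Columns: chrom, start, end, name, score (-log10 p-value), strand ("."),
#' fold_enrichment, n_reads.
#'
#' @param peaks `GRanges` with mcols `score`, `fold_enrichment`, `n_reads`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  stopifnot(is(peaks, "GRanges"),
            all(c("score", "fold_enrichment", "n_reads") %in%
                  names(mcols(peaks))))
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L,
                   end = end(peaks),
                   name = sprintf("peak_%d", seq_along(peaks)),
                   score = round(mcols(peaks)$score, 4),
                   strand = rep(".", length(peaks)),
                   fold_enrichment = round(mcols(peaks)$fold_enrichment, 4),
                   n_reads = mcols(peaks)$n_reads)
  writeLines(paste("# chrom", "start", "end", "name", "score_neglog10p",
                   "strand", "fold_enrichment", "n_reads", sep = "\t"), path)
  write.table(df, path, sep = "\t", quote = FALSE, append = TRUE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED6+2
#'
#' @param path Peak file written by [write_peaks_bed()].
#' @param seqinfo Optional `Seqinfo` attached to the result.
#' @return `GRanges` with mcols `score`, `fold_enrichment`, `n_reads`.
#' @export
read_peaks_bed <- function(path, seqinfo = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    gr <- GRanges()
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 8L)
  if (length(bad))
    stop(sprintf("malformed peak BED line %d in '%s': expected 8 fields, got %d",
                 bad[1], path, lengths(fields)[bad[1]]), call. = FALSE)
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("malformed peak BED line %d in '%s': bad coordinates",
                 bad[1], path), call. = FALSE)
  gr <- GRanges(m[, 1], IRanges(start + 1L, end),
                score = as.numeric(m[, 5]),
                fold_enrichment = as.numeric(m[, 7]),
                n_reads = as.integer(m[, 8]))
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  gr
}

#' Write plain intervals (CpG islands, common peaks) as BED3
#' @param gr `GRanges`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  writeLines("# chrom\tstart\tend", path)
  write.table(df, path, sep = "\t", quote = FALSE, append = TRUE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read plain intervals (e.g. CpG islands) from BED
#' @param path BED file (3+ columns).
#' @param seqinfo Optional `Seqinfo`.
#' @return `GRanges`.
#' @export
read_bed3 <- function(path, seqinfo = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  mcols(gr) <- NULL
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  gr
}

#' Write gene models as 11-column refFlat
#'
#' @param genes Gene-model data frame as held in an `annotated_genome`
#'   (0-based half-open coordinates, list columns `exon_starts`/`exon_ends`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(genes, path) {
  df <- data.frame(
    geneName = genes$gene_name,
    name = genes$tx_name,
    chrom = genes$chrom,
    strand = genes$strand,
    txStart = genes$tx_start,
    txEnd = genes$tx_end,
    cdsStart = genes$cds_start,
    cdsEnd = genes$cds_end,
    exonCount = lengths(genes$exon_starts),
    exonStarts = vapply(genes$exon_starts,
                        function(x) paste0(paste(x, collapse = ","), ","), ""),
    exonEnds = vapply(genes$exon_ends,
                      function(x) paste0(paste(x, collapse = ","), ","), ""))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from an 11-column refFlat file
#'
#' @param path refFlat file.
#' @return Gene-model data frame (see [write_refflat()]).
#' @export
read_refflat <- function(path) {
  raw <- read.table(path, sep = "\t", quote = "", comment.char = "",
                    colClasses = c("character", "character", "character",
                                   "character", "integer", "integer",
                                   "integer", "integer", "integer",
                                   "character", "character"))
  names(raw) <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  parse_blocks <- function(s) lapply(strsplit(s, ",", fixed = TRUE),
                                     function(x) as.integer(x[nzchar(x)]))
  genes <- data.frame(gene_name = raw$geneName, tx_name = raw$name,
                      chrom = raw$chrom, strand = raw$strand,
                      tx_start = raw$txStart, tx_end = raw$txEnd,
                      cds_start = raw$cdsStart, cds_end = raw$cdsEnd,
                      stringsAsFactors = FALSE)
  genes$exon_starts <- parse_blocks(raw$exonStarts)
  genes$exon_ends <- parse_blocks(raw$exonEnds)
  bad <- which(lengths(genes$exon_starts) != raw$exonCount)
  if (length(bad))
    stop(sprintf("malformed refFlat line %d in '%s': exonCount disagrees with exonStarts",
                 bad[1], path), call. = FALSE)
  validate_genes(genes)
  genes
}

#' Write chromosome sizes as a two-column TSV
#' @param seqinfo `Seqinfo` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(seqinfo, path) {
  df <- data.frame(chrom = GenomeInfoDb::seqlevels(seqinfo),
                   size = GenomeInfoDb::seqlengths(seqinfo))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#' @param path chrom sizes file.
#' @return `Seqinfo`.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", col.names = c("chrom", "size"),
                   colClasses = c("character", "integer"))
  make_seqinfo(setNames(df$size, df$chrom))
}

#' Write a qPCR Ct table as TSV
#' @param ct_table Data frame with columns sample, group, gene, replicate, ct.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct_table, path) {
  validate_ct_table(ct_table)
  write.table(ct_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table from TSV
#' @param path TSV with header sample, group, gene, replicate, ct.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_ct_table(df)
  df
}
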