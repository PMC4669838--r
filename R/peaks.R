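#' Remove PCR duplicates: one read per chromosomal position
#'
#' Collapses reads sharing an alignment key to a single representative (the
#' first in coordinate-sorted order), mirroring the standard PCR-bias guard
#' of allowing only one read per chromosomal position. The key is
#' (chromosome, start, strand) by default; `by_strand = FALSE` uses the
#' stricter (chromosome, start) key. The operation is idempotent and
#' independent of input order.
#'
#' @param reads `GRanges` of aligned reads.
#' @param by_strand Include strand in the duplicate key (default TRUE).
#' @return Coordinate-sorted `GRanges` with duplicates removed.
#' @export
deduplicate_reads <- function(reads, by_strand = TRUE) {
  stopifnot(is(reads, "GRanges"))
  if (length(reads) < 2L) return(sort(reads))
  ci <- as.integer(seqnames(reads))
  st <- start(reads)
  sd <- if (by_strand) as.integer(strand(reads)) else rep(0L, length(reads))
  o <- order(ci, st, sd, end(reads)) # end as tie-break: order-independent
  dup <- c(FALSE, diff(ci[o]) == 0 & diff(st[o]) == 0 & diff(sd[o]) == 0)
  reads[o][!dup]
}

#' Binned read coverage
#'
#' Counts deduplicated fragments per fixed-width bin, assigning each
#' fragment to the single bin holding its midpoint, so the total over all
#' bins equals the number of reads (count conservation).
#'
#' @param reads `GRanges` of (deduplicated) fragments.
#' @param seqinfo `Seqinfo` giving chromosome sizes.
#' @param bin_size Bin width in bp (default 200).
#' @return Object of class `coverage_track_set`: list with `bin_size`,
#'   `seqinfo`, and `counts` (named list of integer vectors, one per
#'   chromosome).
#' @export
compute_coverage <- function(reads, seqinfo, bin_size = 200) {
  assert_positive(bin_size, "bin_size")
  chroms <- GenomeInfoDb::seqlevels(seqinfo)
  lens <- GenomeInfoDb::seqlengths(seqinfo)
  nbin <- pmax(1L, as.integer(ceiling(lens / bin_size)))
  f <- droplevels(as.factor(seqnames(reads)))
  ci <- match(levels(f), chroms)[as.integer(f)]
  bad <- which(is.na(ci) | end(reads) > lens[ci] | start(reads) < 1L)
  if (length(bad))
    stop(sprintf("read %d (%s:%d-%d) lies outside the genome",
                 bad[1], as.character(seqnames(reads))[bad[1]],
                 start(reads)[bad[1]] - 1L, end(reads)[bad[1]]),
         call. = FALSE)
  mid0 <- start(reads) - 1L + width(reads) %/% 2L # 0-based midpoint
  bin <- pmin(mid0 %/% bin_size + 1L, nbin[ci])
  by_chrom <- split(bin, factor(ci, levels = seq_along(chroms)))
  counts <- lapply(setNames(seq_along(chroms), chroms), function(i)
    tabulate(by_chrom[[i]], nbins = nbin[i]))
  structure(list(bin_size = as.integer(bin_size), seqinfo = seqinfo,
                 counts = counts),
            class = "coverage_track_set")
}

#' Total reads in a coverage track set
#' @param track `coverage_track_set`.
#' @return Integer total.
#' @export
coverage_total <- function(track) {
  sum(vapply(track$counts, sum, 0))
}

#' @export
print.coverage_track_set <- function(x, ...) {
  cat(sprintf("coverage_track_set: %d chromosome(s), bin %d bp, %d reads\n",
              length(x$counts), x$bin_size, coverage_total(x)))
  invisible(x)
}

#' Call methylation peaks against a supernatant background
#'
#' A simplified Poisson enrichment caller for capture-based methylation
#' data. Captured-fraction counts are summed in sliding windows of
#' `window_bins` consecutive bins (step one bin) and tested against a
#' Poisson null whose mean is the matched background window count scaled to
#' the captured library size, floored at the scaled genome-wide background
#' rate (the local/global-lambda idea of model-based callers, without their
#' fragment-model machinery). Windows at p <= `p_threshold` are merged when
#' separated by at most `merge_gap` bp, merged spans narrower than
#' `min_width` are discarded, and every surviving span is re-scored on its
#' full extent; spans whose recomputed p-value exceeds the threshold are
#' dropped, so each emitted peak individually passes the test it is
#' annotated with.
#'
#' @param captured `coverage_track_set` of the captured fraction.
#' @param background `coverage_track_set` of the supernatant fraction.
#' @param p_threshold Poisson upper-tail p-value cutoff (default 1e-5).
#' @param min_width Minimum peak width in bp (default 400).
#' @param merge_gap Maximum gap bridged when merging significant windows
#'   (default 200 bp).
#' @param window_bins Bins per test window (default 5; with 200 bp bins a
#'   1 kb window, comparable to the expected peak scale).
#' @return `GRanges` of non-overlapping peaks with mcols `score`
#'   (-log10 p-value), `fold_enrichment` (observed/expected) and `n_reads`.
#' @export
call_peaks <- function(captured, background, p_threshold = 1e-5,
                       min_width = 400, merge_gap = 200, window_bins = 5) {
  stopifnot(inherits(captured, "coverage_track_set"),
            inherits(background, "coverage_track_set"))
  if (captured$bin_size != background$bin_size ||
      !identical(names(captured$counts), names(background$counts)))
    stop("captured and background tracks must share bin size and chromosomes")
  assert_probability(p_threshold, "p_threshold")

  n_cap <- coverage_total(captured)
  n_bg <- coverage_total(background)
  if (n_bg == 0 && n_cap == 0) {
    warning("both tracks are empty; no peaks called")
    return(GRanges(seqinfo = captured$seqinfo))
  }
  if (n_bg == 0) {
    warning("background track is empty; using captured genome-wide rate as null")
    scale <- 1
  } else {
    scale <- n_cap / n_bg
  }
  bin <- captured$bin_size
  total_bins <- sum(lengths(captured$counts))
  # genome-wide background rate per bin, scaled to the captured library
  rate <- if (n_bg == 0) n_cap / total_bins else (n_bg / total_bins) * scale

  win_sum <- function(x, w) {
    if (length(x) < w) return(sum(x))
    cs <- cumsum(c(0, x))
    cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
  }

  lens <- GenomeInfoDb::seqlengths(captured$seqinfo)
  peaks <- lapply(names(captured$counts), function(chrom) {
    cap <- captured$counts[[chrom]]
    bg <- background$counts[[chrom]]
    w <- min(window_bins, length(cap))
    wc <- win_sum(cap, w)
    wb <- if (n_bg == 0) rep(0, length(wc)) else win_sum(bg, w)
    lambda <- pmax(wb * scale, w * rate)
    p <- ppois(wc - 1, lambda, lower.tail = FALSE)
    sig <- which(p <= p_threshold & wc > 0)
    if (!length(sig)) return(NULL)
    spans <- IRanges::reduce(
      IRanges((sig - 1L) * bin + 1L, pmin((sig - 1L + w) * bin, lens[chrom])),
      min.gapwidth = merge_gap + 1L)
    spans <- spans[IRanges::width(spans) >= min_width]
    if (!length(spans)) return(NULL)
    # re-score each merged span on its full extent
    cs <- cumsum(c(0, cap)); cb <- cumsum(c(0, bg))
    b1 <- (start(spans) - 1L) %/% bin + 1L
    b2 <- pmin((end(spans) - 1L) %/% bin + 1L, length(cap))
    obs <- cs[b2 + 1L] - cs[b1]
    bg_obs <- cb[pmin(b2 + 1L, length(cb))] - cb[b1]
    lam <- pmax(bg_obs * scale, (b2 - b1 + 1L) * rate)
    logp <- ppois(obs - 1, lam, lower.tail = FALSE, log.p = TRUE)
    keep <- exp(logp) <= p_threshold
    if (!any(keep)) return(NULL)
    GRanges(chrom, spans[keep],
            score = pmin(-logp[keep] / log(10), 9999),
            fold_enrichment = obs[keep] / lam[keep],
            n_reads = as.integer(obs[keep]),
            seqinfo = captured$seqinfo)
  })
  peaks <- peaks[!vapply(peaks, is.null, TRUE)]
  if (!length(peaks)) return(GRanges(seqinfo = captured$seqinfo))
  sort(do.call(c, peaks))
}

#' Deduplicate, bin and call peaks for one simulated sample
#'
#' Convenience wrapper running the captured-vs-supernatant peak call for a
#' library produced by [simulate_mbd_library()].
#'
#' @param reads `GRanges` with mcols `fraction`.
#' @param seqinfo `Seqinfo` with chromosome sizes.
#' @param bin_size Bin width in bp.
#' @param ... Passed to [call_peaks()].
#' @return `GRanges` of peaks.
#' @export
call_sample_peaks <- function(reads, seqinfo, bin_size = 200, ...) {
  fr <- split_fractions(deduplicate_reads(reads))
  call_peaks(compute_coverage(fr$captured, seqinfo, bin_size),
             compute_coverage(fr$supernatant, seqinfo, bin_size), ...)
}
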