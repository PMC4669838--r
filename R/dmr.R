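#' Partition two peak sets into unique (DMR) and common peaks
#'
#' Implements the set-theoretic DMR definition: peaks shared by the two
#' conditions are removed, and the remaining peaks — unique to one sample —
#' are the differentially methylated regions. Two peaks are "shared" when
#' they overlap by at least one bp (default) or, optionally, by at least
#' `min_overlap_frac` of the smaller peak. Shared peaks are merged into
#' cluster-level common intervals, so a chain a1-b1-a2 counts as one common
#' peak; every input peak is accounted for exactly once, either as unique
#' or as a contributor to exactly one common interval.
#'
#' @param peaks_a,peaks_b `GRanges`, each internally non-overlapping.
#' @param min_overlap_frac Minimum overlap as a fraction of the smaller
#'   peak (default 0 = any overlap).
#' @param labels Character pair naming the two sets (default
#'   `c("a", "b")`).
#' @return Object of class `dmr_partition`: list with `unique_a`,
#'   `unique_b` (`GRanges`, original peaks), `common` (`GRanges`, merged
#'   cluster intervals), `labels`, and `counts` (named vector: n_a, n_b,
#'   unique_a, unique_b, common, shared_a, shared_b).
#' @export
partition_peaks <- function(peaks_a, peaks_b, min_overlap_frac = 0,
                            labels = c("a", "b")) {
  stopifnot(is(peaks_a, "GRanges"), is(peaks_b, "GRanges"))
  assert_probability(min_overlap_frac, "min_overlap_frac")
  check_disjoint(peaks_a, "peaks_a")
  check_disjoint(peaks_b, "peaks_b")

  hits <- findOverlaps(peaks_a, peaks_b, ignore.strand = TRUE)
  if (min_overlap_frac > 0 && length(hits)) {
    qa <- peaks_a[queryHits(hits)]; qb <- peaks_b[subjectHits(hits)]
    ov <- IRanges::width(IRanges::pintersect(ranges(qa), ranges(qb)))
    need <- min_overlap_frac * pmin(width(qa), width(qb))
    hits <- hits[ov >= need]
  }
  shared_a <- unique(queryHits(hits))
  shared_b <- unique(subjectHits(hits))
  unique_a <- peaks_a[setdiff(seq_along(peaks_a), shared_a)]
  unique_b <- peaks_b[setdiff(seq_along(peaks_b), shared_b)]
  common <- GenomicRanges::reduce(
    c(granges(peaks_a[shared_a]), granges(peaks_b[shared_b])),
    min.gapwidth = 0L, ignore.strand = TRUE)

  counts <- c(n_a = length(peaks_a), n_b = length(peaks_b),
              unique_a = length(unique_a), unique_b = length(unique_b),
              common = length(common),
              shared_a = length(shared_a), shared_b = length(shared_b))
  stopifnot(counts["n_a"] == counts["unique_a"] + counts["shared_a"],
            counts["n_b"] == counts["unique_b"] + counts["shared_b"])
  structure(list(unique_a = unique_a, unique_b = unique_b, common = common,
                 labels = labels, min_overlap_frac = min_overlap_frac,
                 counts = counts),
            class = "dmr_partition")
}

check_disjoint <- function(peaks, name) {
  if (length(peaks) > 1L &&
      !isDisjoint(GRanges(seqnames(peaks), ranges(peaks))))
    stop(sprintf("'%s' contains overlapping peaks; merge them first", name),
         call. = FALSE)
  invisible(peaks)
}

#' @export
print.dmr_partition <- function(x, ...) {
  cat(sprintf(
    "dmr_partition (%s vs %s): %d unique to %s, %d unique to %s, %d common\n",
    x$labels[1], x$labels[2], x$counts["unique_a"], x$labels[1],
    x$counts["unique_b"], x$labels[2], x$counts["common"]))
  invisible(x)
}

#' Peak counts per chromosome
#'
#' @param peaks `GRanges`.
#' @param seqinfo Optional `Seqinfo`; chromosomes without peaks are then
#'   included with a zero count.
#' @return Data frame with columns `chrom`, `n`; `sum(n) == length(peaks)`.
#' @export
chromosome_distribution <- function(peaks, seqinfo = NULL) {
  chroms <- if (!is.null(seqinfo)) GenomeInfoDb::seqlevels(seqinfo)
            else GenomeInfoDb::seqlevels(peaks)
  n <- table(factor(as.character(seqnames(peaks)), levels = chroms))
  data.frame(chrom = chroms, n = as.integer(n), stringsAsFactors = FALSE)
}

#' Cross-passage peak preservation
#'
#' Fraction of parent-passage (P1) peaks that overlap at least one
#' daughter-passage (D3) peak — the stability measure of the epigenetic
#' mark across cell divisions.
#'
#' @param peaks_p1,peaks_d3 `GRanges`, each internally non-overlapping.
#' @param min_overlap_frac Overlap rule as in [partition_peaks()].
#' @return Object of class `preservation_result`: list with `n_p1`,
#'   `n_preserved`, `fraction`.
#' @export
preservation <- function(peaks_p1, peaks_d3, min_overlap_frac = 0) {
  stopifnot(is(peaks_p1, "GRanges"), is(peaks_d3, "GRanges"))
  if (length(peaks_p1) == 0)
    stop("empty P1 peak set: preservation fraction undefined")
  check_disjoint(peaks_p1, "peaks_p1")
  check_disjoint(peaks_d3, "peaks_d3")
  hits <- findOverlaps(peaks_p1, peaks_d3, ignore.strand = TRUE)
  if (min_overlap_frac > 0 && length(hits)) {
    qa <- peaks_p1[queryHits(hits)]; qb <- peaks_d3[subjectHits(hits)]
    ov <- IRanges::width(IRanges::pintersect(ranges(qa), ranges(qb)))
    hits <- hits[ov >= min_overlap_frac * pmin(width(qa), width(qb))]
  }
  n_pres <- length(unique(queryHits(hits)))
  structure(list(n_p1 = length(peaks_p1), n_preserved = n_pres,
                 fraction = n_pres / length(peaks_p1)),
            class = "preservation_result")
}

#' @export
print.preservation_result <- function(x, ...) {
  cat(sprintf("preservation: %d / %d P1 peaks preserved (%.1f%%)\n",
              x$n_preserved, x$n_p1, 100 * x$fraction))
  invisible(x)
}

#' Chi-square test for two proportions
#'
#' Pearson chi-square on the 2x2 table (k1, n1 - k1; k2, n2 - k2), one
#' degree of freedom, without continuity correction by default — the closed
#' form N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)). Used to compare preservation
#' proportions between lineages.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p_value`, `df`, `proportions`.
#' @export
#' @examples
#' chi_square_proportions(63, 100, 36, 100)
chi_square_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  a <- as.numeric(k1); b <- as.numeric(n1 - k1)
  c <- as.numeric(k2); d <- as.numeric(n2 - k2)
  if ((a + c) == 0 || (b + d) == 0)
    stop("degenerate 2x2 table: a margin is zero")
  n <- n1 + n2
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, proportions = c(p1 = k1 / n1, p2 = k2 / n2))
}

#' Compare preservation between two lineages
#'
#' @param res1,res2 `preservation_result`s (e.g. Dex and control lineages).
#' @param correct Yates correction flag, see [chi_square_proportions()].
#' @return `res1` augmented with a `comparison` element (other lineage's
#'   counts, chi-square statistic, p-value).
#' @export
compare_preservation <- function(res1, res2, correct = FALSE) {
  stopifnot(inherits(res1, "preservation_result"),
            inherits(res2, "preservation_result"))
  ct <- chi_square_proportions(res1$n_preserved, res1$n_p1,
                               res2$n_preserved, res2$n_p1,
                               correct = correct)
  res1$comparison <- list(other_n_p1 = res2$n_p1,
                          other_n_preserved = res2$n_preserved,
                          statistic = ct$statistic, p_value = ct$p_value)
  res1
}

#' Fraction of the genome covered by peaks
#'
#' Genome-level summary used as a proxy for global 5-mC level: total peak
#' bp divided by genome bp.
#'
#' @param peaks Non-overlapping `GRanges`.
#' @param seqinfo `Seqinfo` with chromosome sizes.
#' @return Fraction in `[0, 1]`.
#' @export
global_methylated_fraction <- function(peaks, seqinfo) {
  check_disjoint(peaks, "peaks")
  sum(as.numeric(width(peaks))) /
    sum(as.numeric(GenomeInfoDb::seqlengths(seqinfo)))
}
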