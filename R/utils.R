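#' Derive a stream-specific RNG seed from a global seed
#'
#' All stochastic stages (genome construction, methylation landscapes, each
#' read library, qPCR plates) draw their seed from one global seed plus a
#' stream label, so any single stage can be re-run in isolation and still
#' reproduce the full-pipeline result.
#'
#' @param seed Global integer seed.
#' @param stream Character label of the random stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "genome")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (c in utf8ToInt(stream)) h <- (h * 31 + c) %% m
  as.integer((h + (seed %% m) * 1000003) %% m)
}

# shared argument checks -----------------------------------------------------

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Seqinfo from a named vector of chromosome lengths
make_seqinfo <- function(chrom_sizes) {
  stopifnot(length(chrom_sizes) > 0, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0))
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = as.integer(chrom_sizes))
}

# Rejection-sample non-overlapping intervals of the given widths over a
# genome, keeping >= `gap` bp between placed intervals and avoiding the
# (non-overlapping, coordinate-sorted) `avoid` set. Works in a concatenated
# global coordinate space with plain numeric vectors so placement stays fast
# at thousands of intervals. Returns a GRanges in placement order.
place_intervals <- function(si, widths, gap = 0, avoid = NULL) {
  lens <- as.numeric(GenomeInfoDb::seqlengths(si))
  chroms <- GenomeInfoDb::seqlevels(si)
  offs <- cumsum(c(0, lens))
  n <- length(widths)
  if (sum(widths + gap) > 0.8 * sum(lens))
    stop(sprintf(
      "infeasible packing: %d intervals need %.0f bp but the genome has %.0f bp",
      n, sum(widths + gap), sum(lens)), call. = FALSE)

  av_s <- av_e <- numeric(0)
  if (!is.null(avoid) && length(avoid)) {
    ci <- match(as.character(seqnames(avoid)), chroms)
    av_s <- offs[ci] + start(avoid) - 1
    av_e <- offs[ci] + end(avoid)
    o <- order(av_s); av_s <- av_s[o]; av_e <- av_e[o]
  }
  conflicts <- function(s, e, ks, ke, pad) {
    if (!length(ks)) return(FALSE)
    p <- findInterval(s, ks)
    (p > 0 && ke[p] + pad > s) || (p < length(ks) && e + pad > ks[p + 1])
  }

  kept_s <- kept_e <- numeric(0)
  out_chrom <- integer(n); out_start <- numeric(n)
  for (i in seq_len(n)) {
    w <- widths[i]
    usable <- which(lens > w + 1)
    if (!length(usable))
      stop("infeasible packing: interval wider than every chromosome",
           call. = FALSE)
    ok <- FALSE
    for (try in 1:2000) {
      ci <- usable[sample.int(length(usable), 1,
                              prob = lens[usable])]
      s0 <- floor(runif(1, 0, lens[ci] - w))
      gs <- offs[ci] + s0; ge <- gs + w
      if (conflicts(gs, ge, kept_s, kept_e, gap)) next
      if (conflicts(gs, ge, av_s, av_e, 0)) next
      ok <- TRUE; break
    }
    if (!ok)
      stop("infeasible packing: could not place interval without overlap",
           call. = FALSE)
    p <- findInterval(gs, kept_s)
    kept_s <- append(kept_s, gs, after = p)
    kept_e <- append(kept_e, ge, after = p)
    out_chrom[i] <- ci; out_start[i] <- s0
  }
  GRanges(chroms[out_chrom],
          IRanges(out_start + 1, out_start + widths),
          seqinfo = si)
}
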