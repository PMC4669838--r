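# Brute-force per-base oracles, implemented with plain logical masks in base
# R so they stay independent of the interval machinery they check.
# Coordinates are 0-based half-open throughout.

mask_of <- function(start0, end0, len) {
  m <- logical(len)
  for (i in seq_along(start0))
    if (end0[i] > start0[i]) m[(start0[i] + 1):end0[i]] <- TRUE
  m
}

# per-base partition oracle on one chromosome: returns indices of unique
# a/b peaks and the common cluster intervals
oracle_partition <- function(sa, ea, sb, eb, len, min_frac = 0) {
  na <- length(sa); nb <- length(sb)
  shared_a <- logical(na); shared_b <- logical(nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    ov <- min(ea[i], eb[j]) - max(sa[i], sb[j])
    if (ov <= 0) next
    need <- min_frac * min(ea[i] - sa[i], eb[j] - sb[j])
    if (ov >= need || min_frac == 0) {
      shared_a[i] <- TRUE; shared_b[j] <- TRUE
    }
  }
  # common clusters: sweep-merge the shared peaks by strict overlap
  # (touching half-open peaks share no base and stay separate clusters)
  cs <- c(sa[shared_a], sb[shared_b]); ce <- c(ea[shared_a], eb[shared_b])
  o <- order(cs); cs <- cs[o]; ce <- ce[o]
  com_s <- com_e <- numeric(0)
  for (i in seq_along(cs)) {
    k <- length(com_s)
    if (k > 0 && cs[i] < com_e[k]) com_e[k] <- max(com_e[k], ce[i])
    else { com_s <- c(com_s, cs[i]); com_e <- c(com_e, ce[i]) }
  }
  list(unique_a = which(!shared_a), unique_b = which(!shared_b),
       common_start = com_s, common_end = com_e)
}

# exhaustive primary-context oracle: first context in precedence order whose
# per-chromosome mask intersects the peak
oracle_classify <- function(peaks, feature_map,
                            precedence = c("promoter", "utr5", "utr3",
                                           "exon", "intron")) {
  lens <- GenomeInfoDb::seqlengths(feature_map$seqinfo)
  masks <- lapply(precedence, function(ctx) {
    f <- feature_map$features[[ctx]]
    lapply(names(lens), function(ch) {
      sel <- as.character(seqnames(f)) == ch
      mask_of(start(f)[sel] - 1L, end(f)[sel], lens[[ch]])
    })
  })
  names(masks) <- precedence
  cgi_masks <- lapply(names(lens), function(ch) {
    sel <- as.character(seqnames(feature_map$cgis)) == ch
    mask_of(start(feature_map$cgis)[sel] - 1L,
            end(feature_map$cgis)[sel], lens[[ch]])
  })
  names(cgi_masks) <- names(lens)
  out_ctx <- character(length(peaks)); out_cgi <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    ch <- as.character(seqnames(peaks))[k]
    span <- (start(peaks)[k]):(end(peaks)[k])
    ctx <- "intergenic"
    for (cx in precedence) {
      if (any(masks[[cx]][[match(ch, names(lens))]][span])) { ctx <- cx; break }
    }
    out_ctx[k] <- ctx
    out_cgi[k] <- any(cgi_masks[[ch]][span])
  }
  list(context = out_ctx, cgi = out_cgi)
}
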