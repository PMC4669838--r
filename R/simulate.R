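#' Simulate an MBD-capture sequencing library
#'
#' Emulates methyl-CpG-binding-domain capture of sonicated DNA: fragment
#' start positions are drawn uniformly over the genome, every fragment has
#' the configured sonication length, and each fragment is assigned to the
#' captured fraction with a probability that grows with the methylation
#' level of the region holding its midpoint, or to the supernatant
#' (background) otherwise. The capture model is linear and truncated at 1:
#'
#'   p(capture) = min(1, base_rate * max(1, enrichment * level))
#'
#' so unmethylated DNA is still captured at the non-specific `base_rate`
#' (an empty landscape yields background-rate capture only) and a fully
#' methylated region is enriched `min(1, base_rate * enrichment) / base_rate`
#' fold — an analytically tractable oracle for the expected coverage ratio.
#' Every simulated fragment ends up in exactly one fraction, so
#' captured + supernatant = depth.
#'
#' @param landscape `methylation_landscape` (ground truth for one sample).
#' @param genome `annotated_genome` providing chromosome sizes.
#' @param cfg `lineage_config`; uses `depth`, `fragment_length`,
#'   `base_rate`, `enrichment` and `seed`.
#' @return `GRanges` of aligned fragments with strand and an mcols column
#'   `fraction` (factor: captured/supernatant).
#' @export
simulate_mbd_library <- function(landscape, genome, cfg) {
  stopifnot(inherits(landscape, "methylation_landscape"),
            inherits(genome, "annotated_genome"),
            inherits(cfg, "lineage_config"))
  si <- genome$seqinfo
  set.seed(derive_seed(cfg$seed, paste0("library_", landscape$sample_id)))

  lens <- as.numeric(GenomeInfoDb::seqlengths(si))
  chroms <- GenomeInfoDb::seqlevels(si)
  fl <- cfg$fragment_length
  if (any(lens < fl)) stop("fragment_length exceeds a chromosome length")
  n <- cfg$depth

  eff <- pmax(lens - fl + 1, 0)
  ci <- sample.int(length(chroms), n, replace = TRUE, prob = eff)
  s0 <- floor(runif(n) * eff[ci]) # 0-based starts in [0, len - fl]

  # methylation level at the fragment midpoint (regions are non-overlapping)
  level <- numeric(n)
  regions <- landscape$regions[mcols(landscape$regions)$methylated]
  if (length(regions)) {
    offs <- cumsum(c(0, lens))
    mid <- offs[ci] + s0 + fl %/% 2
    rci <- match(as.character(seqnames(regions)), chroms)
    rs <- offs[rci] + start(regions) - 1
    re <- offs[rci] + end(regions)
    o <- order(rs); rs <- rs[o]; re <- re[o]
    lv <- mcols(regions)$level[o]
    p <- findInterval(mid, rs)
    hit <- p > 0 & mid < re[pmax(p, 1)]
    level[hit] <- lv[p[hit]]
  }

  p_cap <- pmin(1, cfg$base_rate * pmax(1, cfg$enrichment * level))
  captured <- runif(n) < p_cap

  GRanges(chroms[ci], IRanges(s0 + 1, s0 + fl),
          strand = sample(c("+", "-"), n, replace = TRUE),
          fraction = factor(ifelse(captured, "captured", "supernatant"),
                            levels = c("captured", "supernatant")),
          seqinfo = si)
}

#' Split a simulated library into its fractions
#' @param reads `GRanges` with mcols column `fraction`.
#' @return Named list of `GRanges`: `captured`, `supernatant`.
#' @export
split_fractions <- function(reads) {
  stopifnot("fraction" %in% names(mcols(reads)))
  list(captured = reads[mcols(reads)$fraction == "captured"],
       supernatant = reads[mcols(reads)$fraction == "supernatant"])
}

#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold measurements for a multi-group, multi-gene
#' design under the standard exponential-amplification model: a gene with
#' fold-effect f in a group amplifies from f times more template, so its Ct
#' drops by log2(f) cycles relative to baseline. A housekeeping reference
#' gene (HPRT by default) is forced to fold 1 in every group. Optional
#' per-sample offsets model pipetting/loading differences that the
#' delta-Ct normalization must remove.
#'
#' @param design Data frame with columns `gene`, `group`, `fold` (> 0);
#'   one row per gene x group. The reference gene may be omitted (it is
#'   added with fold 1) but if present must have fold 1 everywhere.
#' @param replicates Biological replicates per group (>= 3, default 3).
#' @param noise_sd Gaussian measurement noise on Ct, in cycles.
#' @param sample_effect_sd SD of the shared per-sample Ct offset (default 0:
#'   noiseless designs reproduce the closed form exactly).
#' @param baseline Named numeric of per-gene baseline Cts; genes without an
#'   entry get a draw from U(22, 28).
#' @param reference_gene Housekeeping gene name (default "HPRT").
#' @param seed Integer seed.
#' @return Data frame with columns sample, group, gene, replicate, ct.
#' @export
#' @examples
#' d <- data.frame(gene = "Tet3", group = c("control", "dex"), fold = c(1, 2))
#' simulate_qpcr(d, replicates = 3, noise_sd = 0, seed = 1)
simulate_qpcr <- function(design, replicates = 3, noise_sd = 0.2,
                          sample_effect_sd = 0, baseline = NULL,
                          reference_gene = "HPRT", seed = 1) {
  stopifnot(is.data.frame(design),
            all(c("gene", "group", "fold") %in% names(design)))
  if (any(design$fold <= 0)) stop("fold effects must be > 0")
  if (replicates < 3) stop("at least 3 replicates required (assay run in triplicate)")
  groups <- unique(design$group)
  ref_rows <- design$gene == reference_gene
  if (any(ref_rows) && any(design$fold[ref_rows] != 1))
    stop(sprintf("reference gene '%s' must have fold 1", reference_gene))
  if (!all(groups %in% design$group[ref_rows])) {
    design <- rbind(design[, c("gene", "group", "fold")],
                    data.frame(gene = reference_gene,
                               group = setdiff(groups,
                                               design$group[ref_rows]),
                               fold = 1))
  }
  set.seed(derive_seed(seed, "qpcr"))

  genes <- unique(design$gene)
  base <- setNames(runif(length(genes), 22, 28), genes)
  if (!is.null(baseline)) base[names(baseline)] <- baseline

  grid <- expand.grid(replicate = seq_len(replicates), group = groups,
                      gene = genes, stringsAsFactors = FALSE)
  key <- paste(grid$gene, grid$group)
  fold <- setNames(design$fold, paste(design$gene, design$group))[key]
  if (anyNA(fold))
    stop("design must give a fold for every gene x group combination")
  sample_id <- paste(grid$group, grid$replicate, sep = "_")
  offsets <- setNames(rnorm(length(unique(sample_id)), 0, sample_effect_sd),
                      unique(sample_id))
  ct <- base[grid$gene] - log2(fold) + offsets[sample_id] +
    rnorm(nrow(grid), 0, noise_sd)
  out <- data.frame(sample = sample_id, group = grid$group, gene = grid$gene,
                    replicate = grid$replicate, ct = as.numeric(ct),
                    stringsAsFactors = FALSE)
  validate_ct_table(out)
  out[order(out$gene, out$group, out$replicate), ]
}
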