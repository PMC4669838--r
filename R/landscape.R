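#' Configuration for lineage-structured methylation simulations
#'
#' Bundles the parameters of the simulated study design: a two-condition
#' (control vs dexamethasone) by two-passage (parent P1, daughter D3) layout.
#' Defaults encode the study conditions the pipeline is meant to emulate:
#' cross-passage peak retention of 0.63 in the Dex lineage versus 0.36 in
#' control, and net hypomethylation of the Dex-exposed parent relative to
#' control (`hypo_fraction` of the control regions demethylated).
#'
#' @param retention_dex Probability that a Dex-P1 methylated region is
#'   retained in Dex-D3 (default 0.63).
#' @param retention_control Same for the control lineage (default 0.36).
#' @param hypo_fraction Fraction of control-P1 methylated regions that are
#'   demethylated in Dex-P1 (default 0.65).
#' @param enrichment Capture-probability fold factor of fully methylated over
#'   unmethylated DNA (default 50).
#' @param base_rate Non-specific capture probability of unmethylated
#'   fragments (default 0.02).
#' @param depth Fragments simulated per sample library (default 1e6).
#' @param fragment_length Sonicated fragment length in bp (default 200).
#' @param n_regions Methylated regions planted in the control parent
#'   (default 2400).
#' @param region_width Width of each methylated region in bp (default 1000).
#' @param level_range Range the per-region methylation level is drawn from
#'   (default `c(1, 1)`, i.e. fully methylated regions).
#' @param region_min_gap Minimum gap enforced between planted regions in bp
#'   (default 1000), keeping planted peaks separable after merging.
#' @param seed Global seed for all generator streams.
#' @return A validated list of class `lineage_config`.
#' @export
lineage_config <- function(retention_dex = 0.63, retention_control = 0.36,
                           hypo_fraction = 0.65, enrichment = 50,
                           base_rate = 0.02, depth = 1e6,
                           fragment_length = 200, n_regions = 2400,
                           region_width = 1000, level_range = c(1, 1),
                           region_min_gap = 1000, seed = 1) {
  assert_probability(retention_dex, "retention_dex")
  assert_probability(retention_control, "retention_control")
  assert_probability(hypo_fraction, "hypo_fraction")
  assert_probability(base_rate, "base_rate")
  if (enrichment < 1) stop("'enrichment' must be >= 1")
  assert_positive(depth, "depth")
  assert_positive(fragment_length, "fragment_length")
  assert_positive(n_regions, "n_regions")
  assert_positive(region_width, "region_width")
  if (length(level_range) != 2L || any(level_range < 0 | level_range > 1) ||
      level_range[1] > level_range[2])
    stop("'level_range' must be an increasing pair in [0, 1]")
  structure(list(retention_dex = retention_dex,
                 retention_control = retention_control,
                 hypo_fraction = hypo_fraction, enrichment = enrichment,
                 base_rate = base_rate, depth = as.integer(depth),
                 fragment_length = as.integer(fragment_length),
                 n_regions = as.integer(n_regions),
                 region_width = as.integer(region_width),
                 level_range = level_range,
                 region_min_gap = as.integer(region_min_gap),
                 seed = as.integer(seed)),
            class = "lineage_config")
}

new_landscape <- function(sample_id, condition, stage, regions) {
  structure(list(sample_id = sample_id, condition = condition, stage = stage,
                 regions = regions),
            class = "methylation_landscape")
}

#' Draw the four condition-by-passage methylation landscapes
#'
#' Generates ground-truth methylation for the 2x2 study design. Control-P1
#' receives `n_regions` methylated regions at random non-overlapping
#' positions. Dex-P1 is derived from control-P1 by demethylating a
#' `hypo_fraction` of those regions (net hypomethylation of the exposed
#' parent). Each D3 daughter landscape retains every methylated P1 region of
#' its lineage independently with that lineage's retention probability and
#' redraws the non-retained regions at fresh random positions, so both
#' daughters keep a comparable number of methylated regions while differing
#' in how many coincide with their parent.
#'
#' @param genome `annotated_genome` from [build_genome()].
#' @param cfg `lineage_config`.
#' @return Object of class `landscape_set`: list with the four
#'   `methylation_landscape`s (`control_p1`, `dex_p1`, `control_d3`,
#'   `dex_d3`), the `lineage_config`, and a ground-truth table (see
#'   [truth_table()]). Landscape regions are `GRanges` with mcols
#'   `region_id`, `methylated`, `level`, `origin`.
#' @export
draw_landscapes <- function(genome, cfg) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(cfg, "lineage_config"))
  si <- genome$seqinfo
  set.seed(derive_seed(cfg$seed, "landscapes"))

  base <- place_intervals(si, rep(cfg$region_width, cfg$n_regions),
                          gap = cfg$region_min_gap)
  mcols(base)$region_id <- sprintf("r%05d", seq_along(base))
  mcols(base)$methylated <- TRUE
  mcols(base)$level <- runif(length(base), cfg$level_range[1],
                             cfg$level_range[2])
  mcols(base)$origin <- "placed"
  control_p1 <- base

  dex_p1 <- base
  n_hypo <- round(cfg$hypo_fraction * length(base))
  hypo_idx <- sample.int(length(base), n_hypo)
  mcols(dex_p1)$methylated[hypo_idx] <- FALSE
  mcols(dex_p1)$level[hypo_idx] <- 0
  mcols(dex_p1)$origin[hypo_idx] <- "demethylated"

  derive_d3 <- function(p1, retention, stream) {
    meth <- p1[mcols(p1)$methylated]
    retained <- runif(length(meth)) < retention
    keep <- meth[retained]
    mcols(keep)$origin <- rep("retained", length(keep))
    n_new <- sum(!retained)
    if (n_new > 0) {
      redrawn <- place_intervals(si, rep(cfg$region_width, n_new),
                                 gap = cfg$region_min_gap,
                                 avoid = sort(granges(keep)))
      mcols(redrawn) <- S4Vectors::DataFrame(
        region_id = sprintf("%s_new%05d", stream, seq_len(n_new)),
        methylated = TRUE,
        level = mcols(meth)$level[!retained],
        origin = "redrawn")
      keep <- c(keep, redrawn)
    }
    sort(keep)
  }
  control_d3 <- derive_d3(control_p1, cfg$retention_control, "cd3")
  dex_d3 <- derive_d3(dex_p1, cfg$retention_dex, "dd3")

  out <- structure(list(
    control_p1 = new_landscape("control_p1", "control", "P1", control_p1),
    dex_p1 = new_landscape("dex_p1", "dex", "P1", dex_p1),
    control_d3 = new_landscape("control_d3", "control", "D3", control_d3),
    dex_d3 = new_landscape("dex_d3", "dex", "D3", dex_d3),
    config = cfg, seqinfo = si), class = "landscape_set")
  out$truth <- truth_table(out)
  out
}

#' Ground-truth table of a landscape set
#'
#' One row per region per sample, with condition/passage flags, methylation
#' state and level, and the region's origin (placed, demethylated, retained,
#' redrawn). Coordinates are 0-based half-open, matching the BED outputs.
#'
#' @param landscapes `landscape_set`.
#' @return Data frame.
#' @export
truth_table <- function(landscapes) {
  stopifnot(inherits(landscapes, "landscape_set"))
  rows <- lapply(c("control_p1", "dex_p1", "control_d3", "dex_d3"),
                 function(nm) {
    l <- landscapes[[nm]]
    r <- l$regions
    data.frame(sample = l$sample_id, condition = l$condition,
               stage = l$stage, region_id = mcols(r)$region_id,
               chrom = as.character(seqnames(r)), start = start(r) - 1L,
               end = end(r), methylated = mcols(r)$methylated,
               level = mcols(r)$level, origin = mcols(r)$origin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Methylated regions of a landscape as a plain GRanges
#' @param landscape `methylation_landscape`.
#' @return `GRanges` of the methylated regions only.
#' @export
methylated_regions <- function(landscape) {
  stopifnot(inherits(landscape, "methylation_landscape"))
  r <- landscape$regions[mcols(landscape$regions)$methylated]
  granges(r)
}

#' @export
print.methylation_landscape <- function(x, ...) {
  cat(sprintf("methylation_landscape '%s' (%s, %s): %d regions, %d methylated\n",
              x$sample_id, x$condition, x$stage, length(x$regions),
              sum(mcols(x$regions)$methylated)))
  invisible(x)
}

#' @export
print.landscape_set <- function(x, ...) {
  cat("landscape_set (control/dex x P1/D3):\n")
  for (nm in c("control_p1", "dex_p1", "control_d3", "dex_d3"))
    print(x[[nm]])
  invisible(x)
}
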