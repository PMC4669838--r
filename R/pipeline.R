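#' Default pipeline configuration
#'
#' The study conditions the simulator emulates, as a nested list (also the
#' schema of the YAML config file): a 72 Mb four-chromosome toy genome; 2400
#' methylated regions in the control parent; 65% of them demethylated in the
#' Dex-exposed parent (net hypomethylation, scaled to the reported unique /
#' common peak proportions); cross-passage retention 0.63 (Dex lineage) vs
#' 0.36 (control); 200 bp fragments at one million per library with capture
#' base rate 0.02 and 50-fold methylation enrichment; MACS-like caller
#' settings; a TSS -2000/+500 promoter window; and a qPCR plate with six
#' replicates and 0.2-cycle noise.
#'
#' @param seed Global seed stored in the config.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    genome = list(chromosomes = list(chr1 = 24e6, chr2 = 20e6,
                                     chr3 = 16e6, chr4 = 12e6),
                  n_genes = 400, n_cgis = 300, promoter_cgi_frac = 0.5),
    landscape = list(n_regions = 2400, region_width = 1000,
                     hypo_fraction = 0.65, retention_dex = 0.63,
                     retention_control = 0.36, level_min = 1, level_max = 1),
    library = list(depth = 1e6, fragment_length = 200, base_rate = 0.02,
                   enrichment = 50),
    peaks = list(bin_size = 200, window_bins = 5, p_threshold = 1e-5,
                 min_width = 400, merge_gap = 200),
    annotation = list(promoter_upstream = 2000, promoter_downstream = 500),
    qpcr = list(replicates = 6, noise_sd = 0.2, reference_gene = "HPRT"),
    io = list(write_reads = FALSE)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  for (sec in names(defaults)) {
    if (is.list(defaults[[sec]])) {
      for (k in names(defaults[[sec]]))
        if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- defaults[[sec]][[k]]
    } else if (is.null(cfg[[sec]])) cfg[[sec]] <- defaults[[sec]]
  }
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_to_lineage <- function(config, seed) {
  lineage_config(
    retention_dex = config$landscape$retention_dex,
    retention_control = config$landscape$retention_control,
    hypo_fraction = config$landscape$hypo_fraction,
    enrichment = config$library$enrichment,
    base_rate = config$library$base_rate,
    depth = config$library$depth,
    fragment_length = config$library$fragment_length,
    n_regions = config$landscape$n_regions,
    region_width = config$landscape$region_width,
    level_range = c(config$landscape$level_min, config$landscape$level_max),
    seed = seed)
}

#' Run the full study-design pipeline
#'
#' Executes the end-to-end analysis on synthetic data emulating the 2x2
#' study design: build genome, draw the four methylation landscapes,
#' simulate capture/supernatant libraries, deduplicate, call peaks per
#' sample, partition the P1 peak sets into condition-unique DMRs and common
#' peaks, summarize chromosome and genomic-context distributions, quantify
#' cross-passage preservation per lineage with a chi-square comparison,
#' compute genome methylated fractions, and run the qPCR fold-change and
#' methylation-expression concordance analysis. All stage outputs are
#' written as plain-text BED/TSV/JSON under `out_dir` and indexed in a JSON
#' run manifest.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @param quiet Suppress stage messages (default FALSE).
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  paths <- list()
  stage <- function(name, path) { paths[[name]] <<- path; path }

  write_config(config, stage("config", file.path(out_dir, "config.yaml")))

  say("[genome] building annotated genome")
  genome <- build_genome(
    unlist(config$genome$chromosomes),
    n_genes = config$genome$n_genes, n_cgis = config$genome$n_cgis,
    promoter_cgi_frac = config$genome$promoter_cgi_frac, seed = seed)
  write_refflat(genome$genes, stage("refflat",
                                    file.path(out_dir, "genes.refflat")))
  write_bed3(genome$cgis, stage("cgis", file.path(out_dir, "cgis.bed")))
  write_chrom_sizes(genome$seqinfo,
                    stage("chrom_sizes", file.path(out_dir, "chrom.sizes")))

  say("[landscapes] drawing condition x passage methylation landscapes")
  lcfg <- config_to_lineage(config, seed)
  lands <- draw_landscapes(genome, lcfg)
  write.table(lands$truth, stage("truth", file.path(out_dir, "truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  samples <- c("control_p1", "dex_p1", "control_d3", "dex_d3")
  peaks <- list()
  n_reads <- c()
  for (s in samples) {
    say("[library] simulating and calling peaks for %s", s)
    reads <- simulate_mbd_library(lands[[s]], genome, lcfg)
    if (isTRUE(config$io$write_reads))
      write_reads_bed(reads, stage(paste0("reads_", s),
                                   file.path(out_dir,
                                             paste0("reads_", s, ".bed"))))
    dedup <- deduplicate_reads(reads)
    n_reads[s] <- length(dedup)
    fr <- split_fractions(dedup)
    pk <- call_peaks(
      compute_coverage(fr$captured, genome$seqinfo, config$peaks$bin_size),
      compute_coverage(fr$supernatant, genome$seqinfo,
                       config$peaks$bin_size),
      p_threshold = config$peaks$p_threshold,
      min_width = config$peaks$min_width,
      merge_gap = config$peaks$merge_gap,
      window_bins = config$peaks$window_bins)
    peaks[[s]] <- pk
    write_peaks_bed(pk, stage(paste0("peaks_", s),
                              file.path(out_dir,
                                        paste0("peaks_", s, ".bed"))))
  }

  say("[dmr] partitioning P1 peak sets (control vs dex)")
  part <- partition_peaks(peaks$control_p1, peaks$dex_p1,
                          labels = c("control", "dex"))
  write_peaks_bed(part$unique_a,
                  stage("dmr_control", file.path(out_dir,
                                                 "dmr_unique_control.bed")))
  write_peaks_bed(part$unique_b,
                  stage("dmr_dex", file.path(out_dir,
                                             "dmr_unique_dex.bed")))
  write_bed3(part$common,
             stage("common", file.path(out_dir, "common_peaks.bed")))

  chrom_tab <- do.call(rbind, lapply(samples, function(s)
    cbind(sample = s, chromosome_distribution(peaks[[s]], genome$seqinfo))))
  write.table(chrom_tab,
              stage("chrom_dist", file.path(out_dir,
                                            "chromosome_distribution.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("[annotation] genomic-context distributions of the DMRs")
  fmap <- suppressMessages(build_feature_map(
    genome, c(config$annotation$promoter_upstream,
              config$annotation$promoter_downstream)))
  ctx_tab <- do.call(rbind, lapply(
    list(c("dmr_control", "a"), c("dmr_dex", "b")), function(x) {
      pk <- if (x[2] == "a") part$unique_a else part$unique_b
      do.call(rbind, lapply(c(FALSE, TRUE), function(cgi)
        cbind(peak_set = x[1], restrict_to_cgi = cgi,
              context_distribution(pk, fmap, restrict_to_cgi = cgi))))
    }))
  write.table(ctx_tab,
              stage("contexts", file.path(out_dir,
                                          "context_distribution.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("[preservation] cross-passage peak preservation per lineage")
  pres_dex <- preservation(peaks$dex_p1, peaks$dex_d3)
  pres_ctl <- preservation(peaks$control_p1, peaks$control_d3)
  chi <- chi_square_proportions(pres_dex$n_preserved, pres_dex$n_p1,
                                pres_ctl$n_preserved, pres_ctl$n_p1)
  pres_tab <- data.frame(
    lineage = c("dex", "control"),
    n_p1 = c(pres_dex$n_p1, pres_ctl$n_p1),
    n_preserved = c(pres_dex$n_preserved, pres_ctl$n_preserved),
    fraction = c(pres_dex$fraction, pres_ctl$fraction))
  write.table(pres_tab,
              stage("preservation", file.path(out_dir, "preservation.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  frac <- vapply(samples, function(s)
    global_methylated_fraction(peaks[[s]], genome$seqinfo), 0)
  write.table(data.frame(sample = samples, methylated_fraction = frac),
              stage("global_fraction", file.path(out_dir,
                                                 "global_fraction.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("[qpcr] expression plate and methylation-expression concordance")
  status <- promoter_methylation_status(part, fmap)
  hypo <- status$gene[startsWith(status$status, "hypomethylated")]
  hyper <- status$gene[startsWith(status$status, "hypermethylated")]
  flat <- status$gene[status$status == "unchanged"]
  design_genes <- c(utils::head(hypo, 2), utils::head(hyper, 1),
                    utils::head(flat, 2))
  design_folds <- c(rep(1.8, min(2, length(hypo))),
                    rep(0.6, min(1, length(hyper))),
                    rep(1.0, min(2, length(flat))))
  design <- rbind(
    data.frame(gene = design_genes, group = "control", fold = 1),
    data.frame(gene = design_genes, group = "dex", fold = design_folds))
  ct <- simulate_qpcr(design, replicates = config$qpcr$replicates,
                      noise_sd = config$qpcr$noise_sd,
                      reference_gene = config$qpcr$reference_gene,
                      seed = seed)
  write_ct_table(ct, stage("qpcr_ct", file.path(out_dir, "qpcr_ct.tsv")))
  folds <- fold_change_table(ct, treated = "dex", control = "control",
                             reference_gene = config$qpcr$reference_gene)
  write.table(folds, stage("qpcr_folds", file.path(out_dir,
                                                   "qpcr_folds.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  conc <- concordance_report(folds,
                             status[status$gene %in% design_genes, ])
  write.table(conc, stage("concordance", file.path(out_dir,
                                                   "concordance.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    tool = "mbdpipe",
    version = as.character(packageVersion("mbdpipe")),
    seed = seed,
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0,
                                            units = "secs")), 2),
    config = config,
    outputs = paths,
    counts = list(
      reads_deduplicated = as.list(n_reads),
      peaks = lapply(peaks, length),
      partition = as.list(part$counts),
      preservation = list(dex = pres_dex$fraction,
                          control = pres_ctl$fraction,
                          chi_square = chi$statistic,
                          p_value = chi$p_value),
      methylated_fraction = as.list(frac),
      concordant_fraction = attr(conc, "concordant_fraction")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       force = TRUE)
  paths$manifest <- file.path(out_dir, "manifest.json")
  missing <- !file.exists(unlist(paths))
  if (any(missing))
    stop("manifest references missing outputs: ",
         paste(unlist(paths)[missing], collapse = ", "))
  say("[done] %d stage outputs in %s", length(paths), out_dir)
  invisible(manifest)
}
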