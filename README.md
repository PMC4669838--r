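# mbdpipe

Differential DNA-methylation analysis for methyl-CpG-binding-domain
capture sequencing (MBD-seq / MeDIP-like designs), built for studies that
ask two questions at once: **what does an exposure do to the methylome**,
and **how much of that change survives cell division**. The motivating
design is a glucocorticoid (dexamethasone) exposure of neural stem cells
profiled in the exposed parent culture (P1) and in never-exposed daughter
cells two passages later (D3), in both control and exposed lineages.

The pipeline covers, as plain exported R functions:

* **Peak calling with a matched background** — PCR-duplicate removal (one
  read per chromosomal position), midpoint-binned coverage, and a Poisson
  enrichment test of the captured fraction against the same sample's
  supernatant, scaled by library size: windows of captured counts are
  tested against `Poisson(max(scaled local background, scaled genome-wide
  rate))`, merged, re-scored and thresholded at p ≤ 1e-5.
* **DMR partition** — peaks shared between two conditions (≥ 1 bp overlap
  by default) are removed; the remainder are the differentially
  methylated regions (DMRs) unique to each condition, with shared peaks
  merged into cluster-level common intervals (a Venn-style
  unique/unique/common accounting).
* **Genomic context** — classification of peaks into promoter / 5' UTR /
  3' UTR / exon / intron / intergenic against refFlat gene models, CGI
  overlap, and context distributions normalized per Mb of feature.
* **Cross-passage preservation** — the fraction of P1 peaks overlapping a
  D3 peak, compared between lineages with a 2×2 Pearson chi-square
  (`N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`, 1 df).
* **qPCR expression** — `ΔCt = Ct(target) − Ct(HPRT)` per replicate,
  `ΔΔCt = mean ΔCt(treated) − mean ΔCt(control)`, fold `2^−ΔΔCt`,
  Student's t-test for two groups or one-way ANOVA with gated Bonferroni
  post-hoc for more, and a promoter-methylation / expression concordance
  report.
* **A synthetic-data generator** — annotated toy genome (refFlat + CGIs),
  condition/passage-structured methylation landscapes with configurable
  hypomethylation and retention, MBD-capture read libraries with a
  truncated-linear capture model, and qPCR plates — all with ground-truth
  tables, so every stage is validated against planted signal.

All I/O is plain text: BED6(+2) for reads and peaks, BED3 for CGIs and
common intervals, 11-column refFlat, TSV for Ct tables and reports, YAML
configs, and a JSON run manifest.

## Worked example

Run the whole study design — four samples (control/dex × P1/D3) simulated,
deduplicated, peak-called, partitioned, annotated, preservation-tested and
qPCR-analysed — from one call:

```r
library(mbdpipe)
man <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

With the default configuration (72 Mb genome, 2400 methylated regions in
the control parent, 65% demethylated under exposure, retention 0.63 vs
0.36, 10^6 fragments per library) this prints, via the manifest counts:

```
peaks: control-P1 2276, dex-P1 830, control-D3 2265, dex-D3 817
P1 partition: 1483 control-unique DMRs, 37 dex-unique DMRs, 791 common
preservation: dex 60.5%, control 38.5% (chi-square 119.2, p = 9.5e-28)
genome methylated: control-P1 5.44%, dex-P1 2.27%
```

Reading it: exposure removed roughly two thirds of the parental peak set
(1483 control-unique DMRs against 37 dex-unique — net hypomethylation,
also visible as the genome methylated fraction dropping from 5.4% to
2.3%), and the exposed lineage kept 60.5% of its parental peaks across
two passages versus 38.5% in control — a highly significant difference in
proportions, i.e. the exposure-induced methylation state is
disproportionately stable. The small biases off the configured 0.63/0.36
(caller recall, chance overlap of redrawn regions) are characterized in
the methods vignette.

The qPCR stage (`run1/qpcr_folds.tsv`) ties expression to promoter
methylation for genes picked from the partition:

```
      gene delta_delta_ct fold  p_value
1 gene0001          0.217 0.86 8.72e-02
2 gene0002          0.105 0.93 4.43e-01
3 gene0003         -0.536 1.45 3.13e-03
4 gene0011         -0.835 1.78 1.79e-05
5 gene0359          0.943 0.52 1.61e-04
```

Genes with promoters hypomethylated in dex (gene0003, gene0011) come out
upregulated, the hypermethylated promoter (gene0359) downregulated, and
the unchanged promoters (gene0001/2) near fold 1 — the concordance report
(`run1/concordance.tsv`) scores 3/3 scored genes concordant.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --out-dir run1
```

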