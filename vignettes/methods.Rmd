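---
title: "Methods: simulation and analysis model of mbdpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis model of mbdpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mbdpipe` implements an enrichment-sequencing (MBD-seq) differential
methylation analysis as a fully testable pipeline: PCR-duplicate removal,
binned coverage, Poisson peak calling of the methyl-captured fraction
against the matched supernatant background, set-theoretic DMR partition
between two conditions, genomic-context annotation against refFlat gene
models and CpG islands, cross-passage peak preservation with a chi-square
test of proportions, and qPCR relative expression with a
methylation–expression concordance report. Because raw sequencing data for
this kind of experiment are rarely depositable at desk scale, the package
ships a synthetic-data generator that reproduces the *statistical
structure* of a two-condition (control vs dexamethasone), two-passage
(parent P1, daughter D3) neural-stem-cell design, with complete ground
truth, so every claim the pipeline makes can be checked against planted
signal.

# The simulation model

## Genome and annotation

`build_genome()` places non-overlapping transcripts of 2–20 kb on a small
multi-chromosome genome (default: four chromosomes totalling 72 Mb), each
with 1–8 exon blocks, a CDS inset ~10% from each transcript end (20% of
genes are non-coding, `cdsStart == cdsEnd` in refFlat convention), and
CpG islands of 0.3–2 kb, half of which are centred on a transcription
start site. The TSS-centred fraction matters: promoter/CGI overlap is the
salient feature of mammalian promoters and is what makes the CGI-restricted
context distribution non-trivial.

## Methylation landscapes

Methylation is modelled at *region* granularity, not per-CpG: the unit of
every downstream analysis is the peak/region, and region-level truth keeps
the generator's truth table exactly aligned with peak-level evaluation.
The control parent receives `n_regions` (default 2400) methylated regions
of 1 kb, placed uniformly with at least 1 kb separation so that planted
regions remain separable after peak merging. Defaults encode the study
conditions the pipeline emulates:

* `hypo_fraction = 0.65`: the Dex-exposed parent loses 65% of the control
  regions (net genome-wide hypomethylation). The value is scaled from the
  reported unique/common peak proportions of the P1 comparison, where
  roughly two thirds of the control peak set is absent from the exposed
  sample.
* `retention_dex = 0.63`, `retention_control = 0.36`: each methylated P1
  region is retained in its lineage's daughter independently with the
  lineage's retention probability. Non-retained regions are *redrawn* at
  fresh random positions rather than deleted, so both daughters keep
  comparable numbers of methylated regions — mirroring that both passages
  yield large peak sets — while differing in how many coincide with their
  parent.

A consequence of the redraw model worth knowing: redrawn regions can land
near a parent peak by chance, which inflates observed preservation by
roughly `n_redrawn * (w_P1 + w_D3) / genome_bp` — about 1–3 percentage
points for the control lineage at the default densities. Observed
fractions therefore sit slightly above the configured retention (and
slightly below it through imperfect peak-caller recall); both effects are
well inside the ±5-point evaluation band and are visible in the tests.

## Read libraries

Fragments have the sonication length (200 bp); start positions are uniform
over the genome; each fragment is assigned to the captured or supernatant
fraction by a Bernoulli draw with

```
p(capture) = min(1, base_rate * max(1, enrichment * level))
```

where `level` is the methylation level of the region holding the fragment
midpoint (0 outside regions). The `max(1, .)` term keeps unmethylated DNA
captured at the non-specific `base_rate` — a truncated-linear model with a
closed-form oracle: the expected captured-coverage ratio of a fully
methylated region over background is `min(1, base_rate * enrichment) /
base_rate`. Defaults `base_rate = 0.02`, `enrichment = 50` saturate
capture for fully methylated regions and put ~4% of fragments in the
captured fraction, in the range expected when a small minority of a genome
is methylated. Every fragment ends up in exactly one fraction, so
`captured + supernatant = depth` holds by construction. Reads are emitted
as aligned BED intervals only — sequence simulation and alignment are out
of scope.

## qPCR plates

Cycle thresholds follow the exponential-amplification model: a gene with
fold effect `f` in a group starts from `f`-fold more template, so
`Ct = baseline - log2(f) + sample_offset + noise`. The housekeeping
reference (HPRT) is pinned to fold 1 in every group; per-sample offsets
(pipetting/loading) are exactly removed by the delta-Ct normalization,
which the tests verify as an invariance property.

# The analysis model

## Deduplication and coverage

One read is kept per (chromosome, start, strand) key — the standard guard
against PCR amplification bias; the strand-blind key is available as the
stricter option. Coverage assigns each fragment to the single bin holding
its midpoint (bin 200 bp), which conserves counts exactly and is adequate
when fragments (200 bp) are no wider than bins.

## Peak calling

The caller is a deliberately simple Poisson enrichment test — the
scientific contribution this package supports lives *downstream* of peak
calling, so the caller favours transparency over the machinery of
model-based callers. Captured counts are summed over sliding windows of
`window_bins = 5` consecutive bins (1 kb at the default bin size),
stepping one bin, and tested against a Poisson null with mean
`max(scaled background window count, scaled genome-wide background
rate)`, the background scaled by the captured/supernatant library-size
ratio. Significant windows (p ≤ 1e-5) are merged across gaps ≤ 200 bp,
spans < 400 bp are dropped, and each merged span is re-scored over its
full extent; spans whose recomputed p-value misses the threshold are
dropped, so every emitted peak individually passes the test recorded in
its score.

Windowed testing (rather than per-bin testing) is load-bearing: at the
coverage this design operates at (~0.01–0.015 fragments/bp), a 1 kb
methylated region yields on the order of ten captured fragments. Spread
over 200 bp bins that is ~2 per bin — no per-bin Poisson test can separate
that from background at p ≤ 1e-5 — while a 1 kb window captures the whole
signal against a background mean well below one. The 1 kb scale matches
the region scale of the generator and of CGI-sized methylation domains.

Two calibration facts, both encoded in the acceptance tests:

* On signal-free data the realized per-window false-positive rate of a
  discrete Poisson test is *at most* the nominal level and usually far
  below it (the attainable p-values jump across the threshold), and
  window merging only reduces the peak count further. The calibration
  check therefore asserts the one-sided bound — observed false peaks must
  not exceed the upper 99% binomial envelope of `p_threshold × tests` —
  rather than a two-sided interval whose lower edge a conservative
  discrete test cannot honour.
* Because merging can fuse two peaks into one when the threshold is
  relaxed, peak *counts* are not strictly monotone in the threshold; what
  is monotone, and what the tests assert, is coverage: every peak called
  at a stricter threshold is contained in a peak called at a looser one.

## DMR partition, preservation, chi-square

Two peaks are "shared" when they overlap by ≥ 1 bp — the most permissive
rule, chosen because no stricter criterion is canonical; a minimum
overlap-fraction knob is exposed and preservation is verified to be
non-increasing as the rule tightens. Shared peaks merge into cluster-level
common intervals (one entity per overlapping chain), so reported common
counts are cluster counts; unique peaks keep their original coordinates.
Every input peak is accounted for exactly once, an invariant asserted on
every call.

Preservation is the fraction of a sample's P1 peaks overlapping ≥ 1 D3
peak, computed on full peak sets (not DMRs). Lineages are compared with a
2×2 Pearson chi-square (1 df) in closed form, without continuity
correction by default — counts here are in the hundreds to thousands — and
with a Yates flag for small-sample use.

## Genomic context

Promoters default to TSS −2000/+500 bp (strand-aware; a common convention,
configurable). UTRs are the exonic sequence between transcript and CDS
bounds; introns are transcript minus exons; non-coding transcripts emit no
UTRs. A peak overlapping several contexts takes the highest-precedence one
(promoter > 5' UTR > 3' UTR > exon > intron > intergenic), which keeps
counts additive across contexts; ties inside the winning context go to the
largest overlap, then the leftmost gene. "Normalized to the gene model" is
implemented as peaks per Mb of non-redundant feature bp, with raw counts
always reported alongside, since a per-feature, per-bp and per-gene
normalization are all defensible readings; zero-bp contexts report an
undefined density rather than zero.

## qPCR quantification

Delta-Ct is computed per replicate (target minus reference in the same
well set) and only then averaged per group — this preserves replicate
variance for the t-test; the alternative (differencing group means) gives
identical folds but no variance. The fold is `2^-ddCt` with
`ddCt = mean dCt(treated) − mean dCt(control)`; swapping groups inverts
the fold exactly. Two groups are compared with Student's t-test on
delta-Ct (pooled variance by default, Welch flag available); more than two
with one-way ANOVA followed, only when the omnibus test is significant at
α = 0.05, by Bonferroni-adjusted pairwise t-tests on a pooled SD. Gating
the post-hoc step keeps the family-wise null error at or below α, which a
simulation test verifies.

Concordance labels a gene concordant when promoter hypomethylation meets
upregulation (fold > 1) or hypermethylation meets downregulation;
unchanged/mixed promoters, folds of exactly 1, and genes present in only
one input are unscored rather than forced into a call.

# Evaluation design and problem sizes

The acceptance suite runs at sizes chosen to make each statistical check
sharp yet quick on a single CPU:

* Interval correctness: ≥ 220 random instances (≤ 100 kb, ≤ 50 peaks)
  against per-base brute-force oracles written independently in base R.
* Caller calibration: 100 signal-free simulations of a 10 Mb genome
  (50 000 bins, both fractions Poisson), checked against the one-sided
  binomial envelope described above.
* Planted recovery: 25 regions of 1.5–2.5 kb per seed, 3 seeds, at
  100 000 fragments over 10 Mb with the default capture parameters —
  ≥ 95% of planted regions must be hit by a called peak.
* Preservation and direction: 20 independent landscape/library draws at
  the full default design (72 Mb, 2400 regions, 10^6 fragments per
  library). Mean estimated preservation must sit within ±0.05 of the
  configured 0.63/0.36 (per-run estimates carry ~±0.02 binomial noise
  plus the small biases discussed above, so the mean is the right
  estimand), the chi-square must reject in ≥ 95% of runs, and the
  hypomethylation directions (more control-unique DMRs; lower methylated
  fraction in the exposed parent) must hold in ≥ 95% of runs.
* qPCR recovery: folds 0.4–3 (including 0.46, a knockdown-sized effect)
  at 0.2-cycle noise and 6 replicates. A single plate estimates a fold
  with ~12% (1σ) sampling error, so recovery within ±15% is asserted on
  the average over 8 independent plates — matching how the assay is
  actually replicated.

# What the simulation does and does not show

The generator reproduces the *design* of the emulated study — condition
and passage structure, capture enrichment, background fractions, peak
densities, retention probabilities, assay noise — so green tests show the
pipeline's logic, calibration and recovery are sound under that design.
It does not model CpG-level sequence context, fragment-length variation,
GC or mappability bias, copy-number structure, partial/bimodal
methylation, or biological replicate variance between cultures; absolute
peak counts from real libraries depend on depth and caller settings and
are not comparable across studies. Conclusions about any real dataset
still require the usual QC on that dataset.

# Degenerate inputs and numerical choices

Empty backgrounds fall back to the captured genome-wide rate with a
warning (both-empty yields an empty peak list); peak p-values are computed
on the log scale so scores do not overflow before the 1e-300 range and are
capped at 9999; the chi-square uses double arithmetic throughout (2×2
products overflow 32-bit integers near margins of 50 000); interval files
carry a `#` header line so that a legitimately empty DMR set still writes
a parseable, non-empty file; all randomness flows from one global seed
through documented per-stream derivations (`derive_seed`), so any stage
can be re-run in isolation and reproduce the full-pipeline result.
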