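---
title: "Artificial technical replicates for RNA-seq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial technical replicates for RNA-seq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bootreps)
```

## The problem

A technical replicate — the same RNA library sequenced a second time — tells
you how much of a differential-expression result is machine and sampling
noise rather than biology. Because replicates double sequencing cost they
are rarely produced, so `bootreps` generates them computationally, by three
strategies, and provides the machinery to judge whether the artificial
replicates behave like real ones.

* **FB** resamples the reads of each FASTQ file with replacement:
  `m = round(π·k)` of the `k` original reads, `π ∈ (0, 1]`. At the count
  level this is very close to multinomially resampling the read-to-gene
  assignment, i.e. it re-plays the sampling noise of the sequencer itself.
  It produces a replicate *per sample*.
* **CB** resamples the columns of the count matrix with replacement,
  producing a new realization of the *whole experiment* from existing
  samples. No new expression values are created.
* **MO** mixes columns: each artificial sample is `Σ wᵢ xᵢ` with
  non-negative weights summing to one. Because mixing blends biologically
  independent samples, it emulates new *biological* material rather than a
  technical re-run.

## The models and their assumptions

**Differential expression.** The built-in engine follows the standard
negative-binomial workflow: median-of-ratios size factors; gene-wise
dispersion `α` in `Var(Y) = μ + αμ²`; `log2FC = log2(m₂/m₁)` from normalized
group means, with a 0.5 pseudocount added to both means only when one of
them is zero (zeros stay finite, and fold changes of positive genes remain
exactly invariant to a sample's sequencing depth);
a Wald statistic `log2FC / SE` with the SE taken from the NB variance at the
fitted means; two-sided normal p values; Benjamini–Hochberg adjustment over
the genes with a computable test; selection at `padj < 0.05` and
`|log2FC| > 2`. It is deliberately minimal — no LFC shrinkage, no
independent filtering, no outlier refitting — and a hook
(`read_de_tsv()` / the `de_backend` argument) accepts tables from a full
external engine where those refinements matter.

**Dispersion moderation.** `estimate_dispersions()` is the plain truncated
method-of-moments estimator: pooled within-level residual variance `s²` with
`α̂ = (s² − m̄)/m̄²` on df-weighted level means, truncated at zero. With nine
samples this estimator is extremely noisy (7 residual df) and truncates to
zero for a large share of genes; plugging it straight into the Wald SE makes
the normal reference anti-conservative (measured type-I error ≈ 0.08 at
nominal 0.05 under the package's own null simulation). `nb_wald()` therefore
shrinks the gene-wise estimates toward a fitted mean-dispersion trend
`α(μ) = a₁/μ + a₀` with weight `df/(df + 20)` before they enter the standard
error — the same borrow-strength idea the established NB engines use,
reduced to its simplest form, with the shrinkage weight chosen to match the
strength mainstream engines apply at this sample size. This restores
calibration (measured type-I ≈ 0.06, within the nominal band; a residual
+0.01 comes from the delta-method normal approximation itself, which
persists even with the true dispersion plugged in) while leaving the
reported per-gene dispersion column untouched. Set `moderate = FALSE` for
the raw plug-in.

**Over-representation.** The gene-set step is the one-sided hypergeometric
(Fisher one-tail) test of a selection against GMT sets, intersected with the
DE universe (genes with a computable p value) and BH-adjusted. It is a
deterministic, offline stand-in for web-service enrichment tools; it makes
no attempt to reproduce any particular tool's composite scores.

**Similarity of result lists.** Result lists (raw p values, or absolute
log2 fold changes so that up- and down-regulation rank alike) are compared
by Spearman's ρ with `1 − ρ` as the distance, and clustered with Ward
linkage. Genes with a missing value in any compared list are dropped
listwise so every pairwise correlation uses one shared gene index.

**Overlap and stability.** Selection overlap is reported as the asymmetric
percentage `100·|A∩B|/|A|` (row = reference). Stability cross-tabulates the
reference selection against the number of `B` replicate runs re-selecting
each gene; genes selected in the reference but in few replicate runs are the
fragile calls.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pi` (FB) | 1 | fraction of reads drawn; the grid worth scanning is 1.0, 0.8, 0.75, 0.5 — below ~0.75 the selected-gene lists thin out noticeably |
| `B` | 10 | artificial replicates per strategy; enough to read a 0–B stability table |
| `stratify` (CB) | `TRUE` | resample within condition groups so each replicate keeps both conditions analysable |
| `dirichlet_alpha` (MO) | 1 | weight concentration; smaller values approach column copies, larger values approach the group mean |
| `within_group` (MO) | `TRUE` | mixing across conditions would average away the treatment effect |
| `alpha`, `lfc_threshold` | 0.05, 2 | the selection thresholds used throughout |

## The synthetic generator

`simulate_counts()` emulates the structure of a two-condition infection
experiment with paired technical replicates: 5 infected vs 4 control
samples; gene baseline means `exp(U(log 5, log 500))`; NB biological
variability `α = 0.1`; 10 % DE genes at `|log2FC| = 3` with random sign.
Technical pairing is modelled by drawing a latent gamma expression per
biological sample and emitting R1 and R2 as two conditionally independent
Poisson draws from it (sequencing noise is Poisson at the count level); a
binomial split of one deeper Poisson draw is available as
`technical_model = "multinomial_thin"`. These distributional values are
invented defaults chosen to look like a typical bulk experiment — moderate
overdispersion, a few-hundred-fold expression range — since no real-data
fits ship with the package.

What the generator does *not* emulate: lane and flow-cell effects, GC and
length bias, adapter or duplication artifacts, correlated gene modules, and
genome-scale references (the toy transcriptome holds one distinct random
transcript per gene, and the exact-match quantifier assigns constant-width
reads by hashed window lookup, counting multi-hits as ambiguous). Passing
tests therefore demonstrate internal correctness and the qualitative
behaviour of the three strategies under clean NB noise — not performance on
real libraries, where alignment ambiguity and batch structure add further
variability that only the FB strategy could even in principle propagate.

## Numerical choices and degenerate inputs

* `round()` (half-to-even) maps `π·k` and mixed counts to integers; `m ≥ 1`
  whenever `k ≥ 1`.
* Duplicated bootstrap reads get a `/bsN` id suffix (off by
  `rename_duplicates = FALSE`); emission preserves input file order; quality
  strings are carried verbatim.
* Paired FASTQ mates share one index sample — the only choice that preserves
  pairing.
* Size factors fall back to total-count scaling (warning) when no gene is
  positive in all samples; all-zero genes get `NA` p values and leave the BH
  family; a singleton group under stratified CB is copied unchanged with a
  warning; empty reference sets give 0 overlap and are flagged.
* Ward linkage defaults to the `ward.D2` convention (with `ward.D`
  selectable) since "Ward" is ambiguous across implementations; `hclust`
  supplies the deterministic tie-break.

## Scale of the shipped benchmark

`replicate_benchmark()` — used by the test suite and the acceptance script —
runs the full read-level pipeline for every FB replicate, so its default
problem size is chosen compact: `d = 300` genes/transcripts, `B = 10`
replicates per strategy, ten seeded experiments, all other parameters the
generator defaults above. At that size the comparison is already stable
(FB's p-value lists track the held-out true replicate more closely than
MO's, and FB's dispersion distributions sit nearest the truth, in
essentially every seeded run), and a full ten-seed sweep completes in a few
minutes on one core. The fold-change magnitude of the comparison is not the
point at this scale; only the ordering of the strategies is.

## Known limitations

* The DE engine's normal-reference Wald test is approximate for very small
  counts; extremely low-expressed genes are better judged by the external
  backend hook.
* FB replicates re-draw from the *observed* reads, so they cannot widen the
  gene universe or reproduce lane effects, and they under-represent
  technical variance components that act before counting.
* MO with Dirichlet(1) weights shrinks within-group variance by roughly
  `2/(n+1)`, so its p values are systematically optimistic; this is a
  property of the strategy being studied, not a defect of the engine.
* The exact-match quantifier is for toy transcriptomes only; real data
  should be quantified by an aligner and imported via `read_counts_tsv()`.
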