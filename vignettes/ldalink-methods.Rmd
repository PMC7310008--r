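---
title: "Topic-model de-noising and self-supervised gene-microbe link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-model de-noising and self-supervised gene-microbe link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldalink)
```

## The problem

Paired host-transcriptome and microbiome profiling of the same patient
cohort (on the order of a hundred sputum samples, tens of thousands of
genes, up to a thousand taxa) invites a simple question with a hard answer:
which genes respond to which microbes? Direct column-by-column correlation
is noisy, massively multiple, and blind to non-linear responses — an immune
cell that senses a microbe may switch a transcriptional program on only
above some abundance, producing a step-shaped relationship that a Pearson
screen scores poorly.

`ldalink` implements a pipeline for this setting:

1. **De-noising by topic models.** Both tables are treated as
   bag-of-words corpora — each patient a document, each gene or microbe a
   word whose count is its scaled abundance — and factored by latent
   Dirichlet allocation (LDA) into a patient-topic matrix `theta` and a
   topic-word matrix `phi`.
2. **A self-supervised pseudo-gold standard.** Extreme linear correlations
   between genes and microbes (|r| > 0.4, p < 1e-5) are taken as positive
   links, an equal-sized sample of near-zero pairs (|r| < 0.05) as
   negatives. No external labels are needed.
3. **A topic-feature link classifier.** Each (gene, microbe) pair is
   represented by the gene's topic column of the gene model's `phi`
   concatenated with the microbe's topic column of the microbe model's
   `phi` (length 2K), and a random forest is trained on the pseudo-gold
   labels, validated by strict entity-disjoint cross-validation, and
   applied to all pairs. Pairs with probability > 0.95 are reported as
   high-confidence links.
4. **Companion analyses.** Supervised cell-type deconvolution of the gene
   table (`G = F S'`) by nu-support-vector regression; microbe
   co-abundance networks with community detection and topic labeling;
   taxonomy roll-up and patient clustering.

## The LDA model and its sampler

Counts are first scaled (`scale_counts()`): each abundance is rounded to an
integer (round-half-to-even by default — the conversion rule is otherwise
underdetermined, and banker's rounding is unbiased; a floor variant is
available), divided by 10, floored, and capped at 1000. The cap keeps token
expansion tractable: every unit of count becomes one token.

The collapsed Gibbs sampler integrates `theta` and `phi` out and resamples
each token's topic from its full conditional with that token's counts
removed:

$$
P(z_{mn}=k \mid Z_{\neg(m,n)}, W) \propto
\frac{n^{k}_{\cdot v,\neg} + \beta}{n^{k}_{\neg} + N_v\beta}
\left(n^{k}_{m,\neg} + \alpha\right)
$$

Tokens are visited document-major, token-minor; counts update
incrementally. After sampling, point estimates use the smoothed formulas
`theta[p,k] = (n[p,k] + alpha) / (n[p] + K alpha)` and
`phi[k,v] = (n[k,v] + beta) / (n[k] + V beta)`, so every row is a proper,
strictly positive distribution. The package tests the conditional against a
brute-force evaluation of the collapsed joint (ratio of Dirichlet
normalizers) on tiny corpora, to 1e-10.

**Defaults and why.** `n_topics = 10` follows the pipeline's standard
configuration for real cohorts. The symmetric hyper-parameters default to
`alpha = 0.5`, `beta = 0.1`: a conventional smoothing scale at K around 10
that yields sparse but non-degenerate topics; both are configurable, and
sparsity is primarily controlled through `alpha`. Sweeps default to 1000
with a 500-sweep burn-in. Estimates are taken from the final state by
default, matching the per-state estimator formulas; averaging the
post-burn-in estimates (`average_samples = TRUE`) reduces Monte-Carlo noise
in `phi` and is what the bundled synthetic benchmarks use, at the cost of
blurring label switching if topics are still drifting (with a burn-in half
the run this was never observed on the bundled corpora). Topics are
reported in descending order of total mass; across seeds, label switching
is expected, and recovery tests match topics by best permutation.

Documents with zero tokens after scaling carry no information for the
sampler and are dropped with a warning rather than imputed.

## The self-supervised link classifier

The positive gate uses the **absolute** correlation (|r| > 0.4 with
p < 1e-5): a strong negative association is as real a link as a strong
positive one. Negatives are drawn uniformly (seeded) from the near-zero
pool, once per run — resampling them per cross-validation repeat would mix
label noise into the fold-to-fold variance.

Pair features are the two `phi` columns, each L1-normalized per entity so
that a rare microbe and a dominant one are described by the same simplex
(raw columns are available with `normalize = FALSE`). The forest uses 500
trees, `sqrt(2K)` features per split, and no depth cap; the probability of
a pair is the fraction of trees voting positive, and the high-confidence
flag uses a strict `> 0.95` comparison.

**Strict left-out cross-validation.** Ten percent of the labeled pairs are
held out; every remaining pair that shares a gene *or* a microbe with the
held-out set is removed from the training split, which therefore keeps
slightly less than 90% of the labels. The held-out AUC then measures
generalization to entirely unseen entities, not memorization of a gene's or
microbe's identity. Entity disjointness is asserted on every repeat. A
repeat whose removal empties a class is resampled (bounded retries,
logged). Prediction excludes exact training pairs by default;
entity-level exclusion is available via the `genes`/`microbes` arguments.

## The deconvolution module

`fit_fractions()` solves `G = F S'` per patient by linear nu-SVR over a nu
grid of {0.25, 0.5, 0.75}, picking the nu with the lowest reconstruction
RMSE, clipping negative coefficients, and renormalizing to the simplex —
the convention of signature-based deconvolution tools built on support
vector regression. Mixture profiles are z-scored per patient and the
signature is standardized by its global mean and SD (not per gene or per
cell type, which would erase the relative magnitudes the regression needs).
Fit significance is a permutation p-value: the null distribution of the
reconstruction correlation under `n_perm` random relabelings of the
profile's genes (default 100, so the smallest attainable p is ~0.01).
`expand_signatures()` then solves the same linear model for `S` over all
genes by QR least squares, clipping (and counting) negative inferred
expression. The bundled signature is always a synthetic stand-in from
`gen_mixtures()`; a real sorted-cell reference panel is user-supplied
input.

## Networks

Microbe co-abundance networks connect microbes whose profiles correlate at
or above a cutoff — 0.3 on raw abundance columns and 0.8 on topic-space
columns (each microbe's `phi` column) are the package defaults. Edges keep
positive correlations only ("co-abundance"); a signed mode thresholds |r|.
Modules come from igraph's edge-betweenness (divisive, cut at maximum
modularity — the cut rule must be chosen and maximum modularity is the
standard one), label-propagation (seeded), or fast-greedy algorithms. A
microbe is labeled with every topic for which it ranks in that topic's
top 10 weights; ties at the boundary are all included so the labeling is
deterministic.

## What the synthetic generators emulate

All tests and benchmarks run on seeded generators with retained ground
truth; no cohort data are required or included.

- `gen_lda_corpus()` draws documents from the LDA generative model itself
  with near-disjoint topic supports — the cleanest possible test of the
  sampler's ability to invert the model.
- `gen_linked_tables()` emulates the joint structure the pipeline assumes:
  latent patient topics (Dirichlet(0.3), 5 topics by default) drive both
  tables. Each entity has a mixed topic affinity — 30% of its weight on its
  main topic, the rest an individual Dirichlet draw — plus per-cell
  log-normal noise (SD 0.8), so that unlinked pairs are mostly weakly
  correlated and rarely cross the positive gate, while each entity's
  affinity vector remains recoverable by LDA. Planted links couple
  topic-matched, pairwise-distinct entities: *linear* links track the
  microbe with Gaussian noise calibrated to r of about 0.8 (which passes
  the |r| > 0.4, p < 1e-5 gate essentially always at 115 patients);
  *threshold* links express a 7-fold step above the microbe's 70th
  percentile with log-normal noise solved in closed form so the Pearson
  correlation sits near 0.3, with a bounded redraw that keeps every
  realized |r| below the 0.4 gate — a coupling the linear screen misses by
  construction, yet topic-readable.
- `gen_mixtures()` builds a marker-block signature matrix (condition number
  well below 50 under the defaults), Dirichlet mixing fractions, and bulk
  profiles `F S'` plus relative Gaussian noise.

What these generators deliberately do **not** model: compositionality and
sequencing depth artifacts, batch effects, taxonomic correlation between
related clades, zero inflation beyond what the log-normal tail produces,
and realistic library-size variation. Passing benchmarks therefore
demonstrate the pipeline's correctness and statistical behavior under its
own assumptions, not performance on any particular cohort.

## Benchmark problem sizes and design choices

The bundled benchmarks use 115 patients (the cohort scale the pipeline
targets) with 400 genes, 150 microbes, 120 linear and 20 threshold links
for the link-prediction study, yielding a pseudo-gold standard of several
hundred positives in which every planted linear link appears; the
generator's stress-scale widths (2000 genes, 1000 microbes) remain a
documented option. On synthetic corpora whose latent
dimension is known to be 5, the LDA fits use `n_topics = 5`: topic-number
selection is out of scope, and fitting the known dimension is the correct
design for a recovery experiment (at `n_topics = 10` the sampler splits
true topics, which costs link-prediction accuracy but changes no
conclusion). The deconvolution benchmark uses 60 patients, 8 cell types,
400 signature genes, and 10% noise.

The positive-set size matters for the strict CV: held-out pairs remove
every training pair sharing an entity, so the labeled set must be small
relative to the entity pools (a few hundred positives against hundreds of
microbes), mirroring the real-data regime where strong correlations are
rare — with too many labeled pairs per microbe, entity removal guts the
training split and the CV estimate collapses. Equally, the accuracy
ceiling of the benchmark is set by how much of the positive labels'
variation is explainable from the latent structure: incidental strong
correlations between unlinked entities carry irreducible sampling noise in
their labels, so the benchmark plants enough true couplings that
learnable links dominate the positives. Generators are calibrated once to
that regime and frozen; the calibration notes live in this vignette rather
than in scattered constants.

**Score bimodality.** On strongly topic-pure entities
(`affinity_purity = 1`) the classifier's probabilities are decisively
bimodal — most pairs near 0, a clear mode near 1 — matching the behaviour
expected when structure is sharp. Under the mixed-affinity benchmark the
features carry genuinely intermediate evidence and the histogram is less
polar: mass concentrates at low-but-nonzero probabilities. The bimodality
property test therefore runs in the topic-pure regime; the benchmark tests
measure discrimination (AUC), which is the quantity that matters for
ranking links.

## Numerical choices and degenerate inputs

- Correlation p-values use the two-sided t-transform with n-2 degrees of
  freedom; an exact permutation option exists for small n. Constant
  columns and pairs with n < 3 are flagged missing (never zero) with a
  warning. Missing clinical cells use pairwise-complete deletion with
  per-pair n recorded.
- All pairs tested in one `correlate_tables()` call form one BH family,
  flattened row-major; families are never pooled across calls.
- `rollup_taxa()` routes unmapped leaves to an explicit `unclassified`
  column so per-patient totals are conserved exactly.
- Patient clustering uses Ward linkage (`ward.D2`) on Euclidean distances
  of row-normalized profiles — the common default for compositional
  heatmaps; the choice is configurable only by calling `hclust` directly,
  as the cut is deliberately deterministic.
- Seeds: every stage seed derives from one master seed by a stable string
  hash (`derive_seed()`), making entire runs byte-reproducible.
- Ties in `predict_links()` rankings break lexicographically by
  (gene, microbe); ties at the topic-label rank boundary are all included.

## Known limitations

- Token expansion makes sampler cost linear in total scaled counts; the
  cap of 1000 bounds it, but very dense tables are still expensive — the
  divisor and cap trade resolution against runtime.
- The pseudo-gold standard inherits the biases of linear correlation on
  compositional data; no CLR or partial-correlation correction is applied.
- Negative training pairs are sampled from near-zero correlations, which
  on small cohorts can include truly coupled pairs whose correlation was
  attenuated by noise; the CV AUC absorbs that label noise.
- The deconvolution assumes the signature panel spans the mixture; absent
  cell types are redistributed over the panel rather than detected.
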