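---
title: "Methods: predicting functional miRNA-target links from a differentiation time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting functional miRNA-target links from a differentiation time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

During ex vivo differentiation of bone-marrow progenitors into eosinophils,
microRNA levels change by orders of magnitude while lineage-defining
transcripts (receptors such as IL-5R&alpha; and CCR3, transcription factors
such as GATA-1/2, PU.1 and C/EBP&epsilon;) rise. Because a miRNA represses
transcripts whose 3'UTRs carry sites complementary to its seed, a miRNA whose
abundance falls while a predicted target's transcript rises (or vice versa)
is a candidate functional regulator of that target. `mirlink` implements this
inference chain as a reusable, testable pipeline:

1. **Trajectory selection.** Each miRNA's fluorescence/abundance trajectory
   is normalized to the uncultured-control condition and the miRNA is kept if
   its fold change reaches the selection threshold (default 5-fold, inclusive)
   at any culture timepoint.
2. **Target prediction.** 3'UTRs are scanned for canonical seed sites; each
   site gets a context-style score; per-pair aggregate scores are ranked and
   the strongest tail retained; an optional duplex alignment refines the
   candidates.
3. **Annotation filtering.** Predicted targets are restricted to genes with
   an exact annotation-term link (with minimum evidence) to the biology of
   interest.
4. **Enrichment.** Pathways are ranked by a right-tailed Fisher exact test on
   their overlap with the filtered target set.
5. **Linkage.** A network edge is emitted for a predicted pair whose
   trajectories are significantly anti-correlated (Pearson, default
   two-sided p < 0.05 with r < 0).

## Models and definitions

### Control normalization and differential selection

For entity $i$ and timepoint $t$, replicate signals are combined by the
arithmetic mean (a geometric-mean mode is available) and

$$\mathrm{FC}_{i,t} = \frac{\max(\bar{x}_{i,t},\ f)}{\max(\bar{x}_{i,\mathrm{ctrl}},\ f)}$$

with signal floor $f = 1$ fluorescence unit, which keeps $\log_2$ fold
changes finite at zero/low signal without dropping entities. An entity is
called *up* if $\max_t \mathrm{FC}_{i,t} \ge \theta$ and *down* if
$\min_t \mathrm{FC}_{i,t} \le 1/\theta$ (default $\theta = 5$, boundaries
inclusive). When a trajectory crosses both bounds the direction with the
larger $|\log_2 \mathrm{FC}|$ wins; an exact tie is classified up and flagged
ambiguous. The extreme is taken over the whole trajectory because selection
on a differentiation course concerns any sustained departure from the
uncultured baseline, not only the endpoint; an endpoint-only mode is a flag.

qPCR quantities use the standard $2^{-\Delta\Delta C_t}$ form with replicate
$C_t$ values averaged per (gene, sample) before $\Delta C_t$.

### Seed sites

With $\mathrm{rc}(\cdot)$ the reverse complement, the UTR match strings of a
miRNA are `7mer-m8` $= \mathrm{rc}(\text{positions } 2\!-\!8)$, `8mer` $=$
`7mer-m8` $+$ `"A"`, `7mer-A1` $= \mathrm{rc}(\text{positions } 2\!-\!7) +$
`"A"`, `6mer` $= \mathrm{rc}(\text{positions } 2\!-\!7)$; the terminal
adenosine is required in the UTR regardless of miRNA position 1. Overlapping
windows are resolved by precedence `8mer > 7mer-m8 > 7mer-A1 > 6mer` with
greedy non-overlap acceptance (by precedence, then start), so the 7mer
contained in a reported 8mer is not reported twice. Coordinates are 0-based
half-open on the sense strand, `N` matches nothing, and DNA input is scanned
as its T&rarr;U image.

### Context-style site score

$$s = b(\text{type}) + w_{AU}\,(0.5 - f_{AU}) + w_{pos}\,\frac{\min(d, c)}{c}$$

where $f_{AU}$ is the AU fraction of the pooled up-to-30-nt flanks (0.5 when
both flanks are empty, a neutral adjustment) and $d$ is the distance from the
site midpoint to the nearer UTR end. Defaults: $b = -0.31, -0.16, -0.10,
-0.02$ for 8mer, 7mer-m8, 7mer-A1, 6mer; $w_{AU} = 0.20$; $w_{pos} = 0.10$;
$c = 1500$ nt. **This score is a declared surrogate**: genome-scale rankings
of this kind additionally use cross-species conservation, which requires
alignment resources a desk-scale package should not bundle. The coefficients
are chosen only to preserve the canonical ordering (8mer strongest) and the
two classic local effects (AU-rich flanks strengthen; sites near UTR ends
strengthen); all are configurable and none is an empirical estimate.

### Duplex refinement

A single local-alignment pass (Gotoh dynamic program, affine gaps) of the
reversed miRNA against the UTR window extending 25 nt on each side of a
site, with Watson–Crick pair +5, G:U wobble +2, mismatch &minus;3, gap open
&minus;8, gap extend &minus;2, and pair/mismatch columns doubled when they
involve seed bases (miRNA positions 2–8). Gap penalties are never doubled —
a deliberate simplification that keeps the score interpretable and lets an
exhaustive enumeration oracle verify the DP exactly. A fully complementary
22-nt window scores $7 \times 5 \times 2 + 15 \times 5 = 145$; the default
refinement threshold of 80 therefore requires pairing well beyond a bare
seed match (a perfect 7-pair seed alone contributes 70).

### Retention percentile

Pairs are ranked by aggregate score (sum of non-6mer site scores by default)
and the strongest $(100 - p)\%$ retained, ties at the cut kept (type-1
empirical quantile), with $p = 95$ by default, matching the convention of
keeping the top tail of a genome-scale prediction set. The cut is global
across pairs; a per-miRNA mode is a flag. **Scale matters**: a percentile
this high is meaningful for thousands of scored pairs. On a planted
simulation with a handful of true pairs it would discard true plants by
construction, so closure tests and the bundled acceptance run use the
permissive settings `percentile = 5, refine = FALSE` — this is a property of
desk-scale positive controls, not a tuning of the method.

### Enrichment and linkage

The right-tailed Fisher p-value is the hypergeometric upper tail
$\sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$, accumulated in
log space. The universe defaults to the union of pathway genes (the
knowledge-base universes of commercial tools are proprietary); ties rank by
descending ratio $k/K$, then lexical id. Raw p-values are reported by
default; Benjamini–Hochberg q-values are optional and never change rank
order. The coverage summary reports
$|query \cap \bigcup \text{top-}k\ \text{pathways}|$ as a percentage with
one decimal.

Linkage computes Pearson r between per-timepoint trajectories (log2 scale by
default, since fold-ratios are multiplicative), with the two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; numerically perfect correlations
are reported as $|r| = 1, p = 0$. $n$ is the number of shared timepoints:
replicates are collapsed to timepoint means before correlation, matching how
trajectory-level correlations are usually quoted for small designs. Edges
require a retained target prediction, $r < 0$ and $p < \alpha$ (default
0.05) in the default `negative` mode.

## The synthetic-data generator

`simulation_config()` emulates the bone-marrow culture design: one
uncultured-control condition plus six timepoints sampled every second day
(`d4`…`d14`), three independent cultures, and planted structure at every
level. Defaults (chosen once, as a realistic desk-scale rendering of such a
study, and not revisited):

* 60 miRNAs, 80 genes, 600-nt UTRs;
* 5 planted up-regulated miRNAs (folds 6–50) and 8 down-regulated (folds
  1/6–1/100) — down-dominant, with ~100-fold extremes, as differentiation
  courses of this kind show;
* control baselines log-uniform on 100–5000 fluorescence units; planted
  trajectories ramp log-linearly from baseline to baseline&times;fold at the
  final timepoint (the simplest monotone shape satisfying the endpoint
  contract); multiplicative log-normal noise with &sigma; = 0.2 (natural
  log) per replicate;
* 8 planted seed sites and 8 anti-correlated links (strength 0.95) between
  planted miRNAs and target genes; linked gene log2 trajectories are
  $-s \cdot z(\text{miRNA log2 trajectory}) + N(0, 0.1^2)$, unlinked genes
  independent noise;
* 15 pathways, with the designated pathway receiving 6 planted target genes
  and the remaining pathways drawn from the background (non-planted) genes —
  the planted pathway is thus the only enriched one, making the simulation a
  clean positive control;
* annotation of the planted target genes (always) plus a random fill to 30%
  of genes, with query terms and evidence counts 1–5; a fraction of 0
  disables annotation entirely.

Background UTR sequence is rejection-sampled ("clean background"): offending
unplanted matches to any simulated miRNA's patterns are removed by iterative
point mutation outside planted windows. The default cleans 7/8-mer types
only; `"all"` also cleans 6mers, which is feasible only for small
simulations (the expected number of chance 6mers grows as
$n_{miRNA} \times n_{genes} \times L / 4^6$).

What the generator does **not** emulate: probe-level microarray artifacts
(dye bias, background subtraction, spike-ins), replicate-correlated batch
effects, expression-dependent variance, isoform-specific UTRs, conservation
structure, or annotation noise. Passing closure tests on this generator
therefore demonstrates correctness of the inference chain, not performance
on real array data.

## Numerical and degenerate-input choices

* Signal floor 1.0 unit before ratios; all-missing-control entities dropped
  with a warning.
* Inclusive comparisons at the fold threshold (5.0 counts); exact
  up/down tie &rarr; up + `ambiguous` flag.
* Quantile type 1 (inverse ECDF) for the retention cut so ties at the cut
  are retained exactly.
* Fisher terms summed via log-sum-exp; `k = 0` returns exactly 1.
* Constant trajectories are an error naming the offending entity (not a
  silent `NA`), because a zero-variance series has no defined correlation.
* Empty UTRs, empty edge lists and empty pathway collections produce empty,
  well-formed outputs, not errors.
* Deterministic ordering everywhere: sites by start then type precedence;
  predictions by score then ids; enrichment by p, ratio, id; edges by p then
  ids. Repeated runs are byte-identical.

## Problem sizes used by the test suite

Unit and closure tests use 10–15 miRNAs, 14–20 genes and 300-nt UTRs; the
scanner oracle check uses 200 random 1-kb UTRs &times; 10 miRNAs; the Fisher
exactness check enumerates all universes up to N = 12; the correlation
oracle uses 1000 random short series; noisy-selection and link-recovery
checks use 100 seeds each. The bundled acceptance run uses the full default
design (60 miRNAs, 80 genes). These sizes keep the whole suite under a
minute on a laptop while exercising every code path.

## Known limitations

* The context score is a surrogate; absolute scores are not comparable to
  conservation-aware genome-scale rankings, only the ordering conventions
  are shared.
* The duplex alignment is a single scoring pass, not a thermodynamic folding
  model; it has no 3'-supplementary-pairing bonus.
* With six timepoints, the Pearson test has low power; `alpha = 0.05`
  corresponds to $|r| \gtrsim 0.81$ at n = 6, so weak real links will be
  missed (and the test's normality assumptions are only loosely met at this
  n).
* The annotation filter does no synonym expansion or term-hierarchy
  reasoning; it is an exact-match gate by design.
* The enrichment universe is the pathway-collection union unless overridden,
  which can overstate significance if the true assay universe is larger.

## A worked run

```{r, eval = FALSE}
library(mirlink)
cfg <- simulation_config(rng_seed = 1)
sim <- simulate_dataset(cfg, "sim-inputs")
pcfg <- pipeline_config(
  expression = sim$paths$expression, mirnas = sim$paths$mirnas,
  utrs = sim$paths$utrs, annotation = sim$paths$annotation,
  pathways = sim$paths$pathways, trajectories = sim$paths$trajectories,
  outdir = "sim-out", percentile = 5, refine = FALSE, top_k = 15)
manifest <- run_pipeline(pcfg)
manifest$stage_counts
```

The outputs under `sim-out/` are the tables described in
`?run_pipeline`; `truth.json` next to the inputs holds the planted ground
truth for scoring.
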