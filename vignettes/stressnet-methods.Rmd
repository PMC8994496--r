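---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

stressnet implements an end-to-end analysis of a two-muscle bovine
microarray experiment contrasting animals slaughtered under physical and
emotional stress with animals handled under limited stress, together with
a synthetic-data generator that makes every stage testable without the
original arrays or any proprietary resource. This vignette documents the
statistical models, the tunable parameters, the numerical choices, and the
places where the design was genuinely open.

## Normalization

Raw intensities are positive fluorescence values on a 10,064-probe array
of which 1,614 probes are non-biological controls. Cells failing
feature-level QC are set to missing and probes failing everywhere are
dropped (`qc_filter()`). Normalization is a two-stage median scaling
(`normalize_probes()`):

1. every value on an array is divided by the median intensity of that
   array's control probes (removing the per-array scale);
2. every stage-1 value is divided by that probe's median across all
   arrays (centring each probe at 1).

Probes with any remaining missing value are then removed and a log2
transform is applied. The stage-2 divisor is computed on stage-1
(control-normalized) values, reading the two steps as sequential; the
alternative (dividing raw values twice independently) differs only by a
per-array constant that the first step already removes.

A consequence of sequential median scaling worth stating explicitly: after
the second, per-probe division, the per-array median over *control probes*
is no longer exactly 1 on the final scale — each probe has been rescaled
individually. The two median contracts therefore hold exactly on the stage
where each is defined: the control median equals 1 on the stage-1 scale
(recorded in the provenance) and the per-probe cross-array median equals 1
on the final pre-log scale. `check_normalization()` verifies both to
1e-9. Normalization is exactly invariant to rescaling any single array.
Medians use the standard midpoint convention for even counts, which makes
the whole stage deterministic.

## Differential expression

Each muscle is fitted separately, since the study design reports
muscle-wise DEG lists. For one muscle there are 32 arrays (16 stressed, 16
limited-stress animals, each group split 8/8 across the two diets). The
per-probe linear model codes stress and diet as centred ±0.5 covariates
with their interaction, so the stress coefficient is the stress − limited
mean difference averaged over diets. An optional additive batch covariate
is available for designs with a known nuisance factor; it is off by
default because no such factor is defined for the synthetic data. All
probes are fitted in one matrix operation (`fit_probe_models()`).

Variances are moderated by empirical Bayes (`moderate_t()`): the prior
`(d0, s0²)` is estimated by moment-matching the log sample variances
against the theoretical scaled-F distribution (digamma/trigamma matching,
with the trigamma inverted by Newton iteration), the posterior variance is
`s̃² = (d0·s0² + df·s²)/(d0 + df)`, and the moderated t is referred to a t
distribution with `d0 + df` degrees of freedom. When the observed
variances are near-homogeneous the moment excess is non-positive and `d0`
is clamped at 1e6 — numerically a fixed-variance normal reference; the
clamp keeps the digamma inversion stable. The two degenerate limits are
exercised in the tests: `d0 = 0` reproduces the ordinary t exactly, and
`d0 = 1e12` pins the posterior variance at the prior. On heterogeneous
variance simulations the estimated prior agrees with `limma::fitFDist` to
1e-6; limma is used only as an independent cross-check, never as the
implementation.

P-values are BH-adjusted across probes (`adjust_bh()`, a validated wrapper
over the standard step-up). A gene is called differentially expressed when

* at least 80% of its probes are significant at adjusted p < 0.10
  (boundary included: 4 of 5 probes passes), and
* all of its probe log2 ratios share one sign.

The gene-level effect is the median probe log2 ratio — robust, and left
unspecified by the calling rule itself. Lowering alpha can only shrink the
DEG set (monotonicity, tested). Probes mapping to more than one gene are
rejected: the probe→gene map must be functional.

## Over-representation tests

GO enrichment (`enrich()`) is a one-sided hypergeometric upper-tail test
of each term in the query list against the background universe of genes
represented on the array (probes collapsed to genes, since the gene is the
annotation unit). Query genes absent from the background are dropped with
a warning. BH correction is applied within each namespace (BP and MF are
reported separately), terms with no query hit are skipped before testing,
and significance is declared at FDR < 0.08. No term-size floor or ceiling
is imposed — none is part of the method definition — but the threshold is
a plain argument.

Cis-transcriptional-module over-representation (`tabulate_modules()`,
`fisher_one_sided()`, `select_modules()`) compares the DEG promoter hits
of each module against the whole-array gene set with a one-sided Fisher
test. The counting unit is the gene: a gene counts once however many of
its promoters match, which is the conservative reading when a gene has
several promoters. The module *occurrence* is the total number of match
positions over the query genes' promoters, which can exceed the target
gene count. Selection is strict (p < 0.1); a module at exactly 0.1 is
excluded. Genes without a usable promoter should be removed from both
query and universe before tabulation — the function signature makes the
universe explicit for exactly this reason.

## Network extraction

The interaction database is a directed edge list with per-edge
bibliographic reference counts; a node's *relations* are its total
incident edges (either direction, any type). Around a seed set,
`extract_network()` admits:

* **regulators** — nodes with `Regulation` edges into at least 2 seeds,
  a maximum seed-edge reference count ≥ 3 and degree ≥ 2 (per-muscle
  profile) or ≥ 5 (common-network profile);
* **expression targets** — nodes receiving `Expression` edges from at
  least 2 seeds, with ≥ 3 references on at least one such edge and
  degree ≥ 6.

Three readings were genuinely open and are resolved as explicit,
configurable choices (`filter_params()`): "common to them" is ≥ 2 seed
connections (the weakest non-trivial reading); the reference threshold is
satisfied by any single qualifying edge (per-edge maximum rather than a
sum); and relation counts include both directions and both edge types.
Edge direction conventions — `Regulation` points regulator→gene,
`Expression` points gene→target — are needed to separate the two roles.
Raising any threshold can only remove admitted nodes (tested against a
brute-force scan of every node).

`major_nodes()` intersects the regulator (or target) sets across the
per-muscle and common networks, which is how the core regulators and
targets of the stress response are defined.

## QTL mapping

Genes map to QTLs by strict interval containment: same chromosome and the
gene interval entirely inside the QTL interval, with endpoint equality
counting as contained ("entirely included" is naturally non-strict).
Strand is ignored — containment is strand-symmetric. All coordinates are
normalized to 0-based half-open at load time (BED is read as-is; 1-based
inclusive tables are shifted), so a single internal convention prevents
off-by-one drift. The overlap search delegates to GenomicRanges and is
verified against an all-pairs scan. Which trait names count as "meat
quality" is supplied by the `trait_class` column of the QTL table, not
hard-coded.

## The synthetic-data generator

`simulate_dataset()` fabricates every pipeline input with planted ground
truth. The generative model for intensities is log-normal: Gaussian on the
log2 scale with probe baselines ~ N(10, 1.5), a per-array multiplicative
scale effect (log2 sd 0.1), i.i.d. measurement noise (log2 sd 0.2), and a
signed log2 effect drawn from [1, 2] added to the probes of each planted
DE gene in the stressed samples of its designated muscle(s). The
log-normal choice matches the ratio-based normalization the pipeline
applies; the intensity distribution itself is a modelling decision, not a
measured property. Control probes receive the array effect and the noise
but never a biological effect, so they are usable for normalization
exactly as intended.

Defaults emulate the study conditions: 10,064 probes (1,614 controls),
4,210 genes with 1–3 probes each, 2 muscles × 2 stress groups × 2 diets
with 32 animals (one array per animal per muscle), and 70 planted DE genes
split 38 LT-only / 8 ST-only / 24 common — the proportions of the
muscle-specific and core responses. Per-cell QC failures occur at rate
0.002; because normalization removes any probe with a missing value, and
each probe is observed on 64 arrays, this retains ≈88% of probes, the
mild filtering regime of a well-behaved array batch. Planted module target
sets, network regulators/targets (with decoys each violating exactly one
admission filter), QTL-spanning genes and an enriched annotation term give
every downstream stage a recoverable signal; all reference counts in the
synthetic database follow a shifted geometric distribution, heavy-tailed
like literature-curation counts.

All randomness flows from a single integer seed through fixed per-stage
sub-streams, so identical (seed, config) pairs produce byte-identical
output files.

What the generator does *not* emulate: probe-sequence effects and
cross-hybridization, spatial array artifacts, correlated QC failures,
intensity-dependent variance, annotation incompleteness, and the
promoter-quality tiers of real promoter databases. Passing recovery tests
on synthetic data therefore demonstrates the correctness and calibration
of the pipeline's logic under its stated model, not performance on raw
arrays.

## Calibration and problem sizes

The test suite checks, among others:

* exact reproduction of the published list arithmetic from the bundled
  study tables (DEG/module/regulator/target/QTL counts);
* oracle equivalence of the hypergeometric tail (exhaustive grid up to
  N = 60), BH (1,000 random vectors), QTL containment (10,000 random
  pairs) and network extraction (databases up to 200 nodes);
* null calibration: with no planted effects (5,000 probes, 16 animals
  per group), probe-level p-values pass a KS < 0.03 uniformity check in
  ≥ 90% of 100 seeds, and the fraction of seeds with any false DEG call
  stays within the binomial envelope of the BH level;
* recovery: at the default configuration, ≥ 90% of planted DE genes and
  modules and 100% of planted regulators/targets are recovered with no
  decoy admitted, across 50 seeds.

These problem sizes keep the complete suite under a few minutes on one
CPU while leaving the Monte-Carlo error of each rate well below the
margin it is compared against.

## Known limitations

* The model term for the study's "period" factor is undefined in the
  source design; it is available as an optional additive batch covariate
  but never guessed.
* The 80% probe-consistency rule is applied per gene identifier; if a
  gene had probes for several transcripts they are pooled.
* The enrichment stage takes the annotation table as-is and does not
  propagate terms up the GO graph.
* No background subtraction or spatial correction is attempted; QC is an
  input flag, not a computation.
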