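---
title: "Methods: correlation networks, promoter enrichment, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation networks, promoter enrichment, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`drynet` implements an integrated analysis of two-treatment developmental
multi-omics data from grape berries under deficit (`D`) versus full (`C`)
irrigation: stage-wise treatment response, condition-specific metabolite
correlation networks with a permutation null, merged metabolite–transcript
association networks, and promoter motif / GO-slim enrichment. This
vignette records the statistical model behind each stage, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the numerical and design choices made where the procedure
was genuinely underdetermined.

## Stage-wise treatment response

For each metabolite and sampling stage (days after anthesis, DAA) the
package reports `log2FC(D/C) = log2(mean_D / mean_C)` of the raw
concentrations and a two-group one-way ANOVA between treatments at that
stage (F with 1 and `n_C + n_D − 2` degrees of freedom; with two groups
F equals the square of the pooled-variance t statistic). Each sampling
point is tested at the nominal level (default `alpha = 0.05`) with no
multiple-testing correction across metabolites or stages — the per-point
usage this analysis tradition follows. Both statistics are computed on raw
concentrations; whether a transform should precede them is not fixed by the
tradition, and raw values keep `log2FC` interpretable as a concentration
ratio. Degenerate inputs (zero pooled within-group variance, as arise in
noise-free simulations) are flagged: equal means give F = 0, p = 1;
unequal means give p = 0 with `degenerate = TRUE`.

## Condition-specific correlation networks

Within each condition's samples the similarity index is the Pearson
correlation (PCC) of raw concentrations (`log_scale = TRUE` switches to
log abundances). An edge is kept when `|r| > r_min` **and** the
permutation p-value is below `alpha`, with defaults `r_min = 0.8`,
`alpha = 0.001`, `B = 2000` — the standard gate for this analysis.

Numerical choices for the permutation null:

* **Two-sided on |r|**, since published networks of this kind display both
  positive and negative edges.
* **Per-pair permutation** of one variable's sample labels, rather than a
  single joint row permutation, with `p = (#{b : |r_b| >= |r_obs|} + 1) /
  (B + 1)`. The +1 correction makes the smallest attainable p exactly
  `1/(B+1)` (≈ 0.0005 at B = 2000, so the p < 0.001 gate is attainable;
  `validate_config()` flags combinations where it is not). Ties
  `|r_b| = |r_obs|` count toward the exceedance set (conservative).
* **Per-pair RNG substreams** derived by hashing `(seed, feature_a,
  feature_b)`, so results are independent of the order in which pairs are
  evaluated and of how many other features exist.
* **Gate conjunction shortcut**: the permutation test is run only for pairs
  already exceeding `r_min` (in `top_correlators()`, permutation is
  additionally stopped early once the exceedance count can no longer
  satisfy `p < alpha`). Because the gate is an AND, the resulting edge
  sets, reported p-values of retained edges, and all summaries are
  identical to the exhaustive computation; only wasted permutations are
  skipped. The early-stopping stream is consumed in fixed-size chunks from
  the pair's substream, so decisions remain deterministic.
* **Zero-variance features** are kept as isolated nodes and reported with a
  warning rather than aborting the run.

Topology metrics follow the Cytoscape network-analyzer conventions used
when such networks are summarised: average degree ("average node
neighborhood") over nodes of degree ≥ 1; mean local clustering coefficient
over connected nodes with degree-1 nodes contributing 0; density =
2E / (n(n−1)) over connected nodes. Empty networks report zeros.

## Metabolite–transcript integration

The metabolite (2 treatments × 6 stages × 4 replicates) and transcript
(2 × 3 × 3) designs differ, so merging needs an explicit sample alignment.
The default, `replicate_pairing`, restricts both assays to shared
(treatment, stage) cells and pairs replicate *i* with replicate *i* up to
the smaller replicate count (18 aligned samples by default); it preserves
replicate-level variation. `stage_means` (6 aligned samples) averages
replicates and is offered for designs whose replicates are not exchangeable
between assays. Since no replicate correspondence is canonical, pairing by
index is a declared convention, not an inference.

Per target metabolite, genes passing the permutation gate (`alpha = 0.001`,
same `B`) are ranked by `|r|` — gate-then-rank, with ties broken by gene ID
so output is deterministic — and the top `k = 100` are kept. Correlation is
computed jointly across the merged C+D samples by default (`condition`
restricts to one treatment); joint correlation matches the "merged
matrices" phrasing of the tradition and favours associations stable across
treatments. Overlap accounting reports exact Venn counts (specific to one
metabolite, shared by exactly each pair, shared by all); pathway tallies
count positive and negative links per pathway, with unmapped genes under
`"unannotated"`.

## Promoter motif and GO-slim enrichment

Promoters are 1-kb sequences; motifs are degenerate IUPAC consensi
(PLACE-style). A promoter is *associated* with a motif when it contains at
least one match on either strand (cis-elements are generally functional in
either orientation; `both_strands = FALSE` is available per call).
Scanning uses `Biostrings` with the pattern degeneracy active and the
subject read literally, so an `N` in a promoter is matched only by an `N`
in the motif. Overlapping matches all count, but enrichment uses
presence/absence only.

Enrichment of a gene set of size `n` against a background of `N` promoters
is the hypergeometric upper tail `P(X >= k)` with `K` associated promoters
in the background and `k` in the set. Motif calls follow the raw-p rule —
significant iff `p < 0.01` **and** `k >= 10` promoters — with no FDR
correction, while GO-slim terms use Benjamini–Hochberg FDR < 0.05; the
asymmetry mirrors the analysis tradition this package reimplements. The
enrichment score is `−log10 p` (score 2 at p = 0.01, 4 at p = 0.0001),
the only mapping consistent with how such heatmaps are annotated.

## The synthetic study and its ground truth

The generator emulates the statistical structure the analyses assume, at
the exact factorial design of the measured study (six metabolite stages
27–93 DAA × 4 replicates, three transcriptome stages × 3 replicates, two
treatments, 74 metabolites, 2,000 genes by default):

* **Log-normal abundances.** Feature log-abundance is a smooth latent
  trajectory plus Gaussian noise (`noise_sd = 0.15` log units);
  concentrations are positive and right-skewed, as measured ones are.
* **Planted modules.** Module members share a module latent trajectory
  with coupling `loading` (default 0.9) in the conditions given by
  `treatment_coupling`. `D_only` modules — members coherent under deficit,
  weakly idiosyncratic under control — are how the generator realises
  treatment-dependent densification; the default configuration plants one
  constitutive 8-metabolite module and two deficit-only modules (6 and 5).
* **Distinct developmental programmes.** Module latents are random cubics
  in normalised stage, orthogonalised across modules on the stage grid
  (the centered cubic space on six stages holds at most three mutually
  orthogonal programmes). Background and uncoupled-member trajectories are
  drawn from a degree-5 orthogonal-polynomial basis and then projected
  orthogonal to every module latent, with small amplitude
  (`background_loading = 0.08` log units). Both choices address the same
  hazard: with only six stages, two independent smooth curves align by
  chance alarmingly often, and under the exponential (raw-concentration)
  scale a strongly varying module member correlates spuriously with any
  weakly aligned background feature. Orthogonal programmes plus
  noise-scale background amplitude keep non-planted |PCC| structurally
  below the 0.8 gate, so false edges are rare at any seed rather than by
  luck of one seed.
* **Treatment effects.** A planted log2FC (default 1) is added to D
  samples at ripening stages (≥ 65 DAA, the veraison boundary) for the
  members of deficit-only modules — the drought-induced, drought-rewired
  compounds — or for an explicit `effect_features` list. For features
  whose C and D trajectories coincide the planted value is exactly the
  expected stage log2FC; for D_only members the treatment contrast also
  contains their trajectory difference. Background features share one
  trajectory across treatments and are therefore true nulls for the
  stage-wise ANOVA (its type-I rate is checked against the nominal level).
* **Gene–metabolite links.** Each linked gene tracks its partner
  metabolite's log-mean trajectory in both conditions, so joint-sample
  correlation (the integration default) recovers planted links; remaining
  genes follow weak independent trajectories.
* **Promoters and motifs.** Random sequences at `gc_content = 0.35`
  (plant-promoter-like AT richness); each planted motif instance
  (degenerate positions resolved uniformly, random strand, uniform
  position, never overwriting an earlier planted site) is inserted with
  probability 0.8 into the 100 regulon promoters and 0.05 elsewhere. The
  bundled 30-element library uses PLACE-style consensi; the planted
  defaults (DRECRTCOREAT, MYCATRD22, RYREPEATBNNAPA) are drought/ABA
  elements, the rest serve as decoys. Note that elements sharing consensus
  (e.g. LTRECOREATCOR15 = CCGAC inside DRECRTCOREAT = RCCGAC) are
  genuinely co-enriched wherever the longer element is planted — the same
  phenomenon consensus-sharing asterisks mark on published enrichment
  heatmaps — and are therefore not decoys.
* **Determinism.** One master seed is hashed with named labels into
  substreams (trajectories, noise, promoters, regulon, DE flags, per-pair
  permutations), so every artifact is bit-reproducible and, e.g., adding
  genes does not perturb the metabolite draws.

What the generator does **not** emulate: count-based sequencing noise
(transcripts are log-normal, not negative-binomial), missing values,
batch/replicate random effects, heteroscedastic measurement error across
the concentration range, LD-like correlation among motif occurrences, and
any physiological coupling between metabolites and berry ripening state.
Passing recovery tests therefore demonstrates that the pipeline's
inference machinery is correct under its own assumptions, not that those
assumptions hold for a particular instrument or vineyard.

## Validation problem sizes

The test-suite checks run at desk scale, chosen to keep the full suite in
a few minutes: statistical-core oracles on closed-form examples and ~100
random cases; topology against brute-force enumeration on 200 random
graphs of ≤ 12 nodes; permutation calibration on 1,000 independent
Gaussian pairs (n = 24, B = 500); planted-structure recovery on the
default 74 × 48 / 2000 × 18 dataset with B = 2000; the
deficit-densification contrast over 100 seeds; and byte-identity of
pipeline reruns. The same quantities are recomputed from scratch by
`scripts/acceptance.R` under any user-supplied seed.

## Known limitations

* With six stages, at most three mutually orthogonal smooth module
  programmes exist; configurations with more strong modules will show
  cross-module correlation.
* The permutation null tests exchangeability of sample labels, not
  independence of the underlying developmental processes; two features
  sharing a genuine smooth trajectory are *correctly* called correlated
  even if that trajectory is biologically incidental.
* `stage_means` alignment with the default design yields n = 6, near the
  minimum for stable correlation estimates; prefer `replicate_pairing`
  unless replicates are non-exchangeable.
* Hypergeometric enrichment assumes promoters are exchangeable; GC or
  length biases in real promoter sets are not modelled.
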