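---
title: "Methods: consensus differential presence of exons in cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus differential presence of exons in cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the unit of analysis

Liquid-biopsy whole-exome sequencing of plasma cell-free DNA yields a
fragment count per exon per sample. The working hypothesis is that
tumors release DNA non-uniformly, so the *presence* of individual
exons in plasma — not their expression — separates metastatic (M),
non-metastatic (N) and healthy (H) cohorts, with an unclassifiable
(U) group expected to share features of M and N. `dpescan` calls an
exon *differentially present* (DPE) when two different
negative-binomial GLM tests agree at a strict FDR, and defines an
exonic signature as the intersection of the DPE sets across the three
cohort comparisons (M vs N, C vs H with C = M ∪ N, M vs H).

## Counting and preprocessing

Counting follows union semantics on fragments: all alignments sharing
a query name form one fragment; a fragment overlapping exactly one
exon id adds one count there, a fragment touching two or more
distinct exons is ambiguous and counted nowhere. Fragments, not
mates, are the unit because a cfDNA molecule is the biological
observation. Secondary, supplementary and duplicate-flagged
alignments are skipped and a mapping-quality floor (default 10)
applies; the source tooling convention is silent on both, so these
are exposed flags, not fixed truths. Internally all coordinates are
0-based half-open; GTF is converted on read so no other code path
ever reasons about coordinate conventions.

Preprocessing runs in a fixed order: sex-exon removal → library-size
recomputation → low-presence filter → TMM. Removing chromosome X/Y
exons first and recomputing depths keeps library sizes free of
sex-composition differences (cfDNA cohorts otherwise ordinate by
patient sex). The exact sex-exon list used by the original analysis
was never published; chromosome-based removal is this package's
proxy. The low-presence filter implements the literal rule: an exon
is *removed* when its CPM falls below `min_cpm` (default 1) in at
least `min_samples` (default 20) samples. The more common inverted
convention (keep when enough samples reach the threshold) is
available as `convention = "keep-if-expressed"`; the two differ on
exons that narrowly straddle the threshold. Library sizes are *not*
recomputed after this filter — they reflect the assay's depth, and
keeping them fixed also makes the filter idempotent.

TMM normalization follows the published trimmed-mean-of-M-values
definition exactly: reference sample by upper-quartile CPM closest to
the mean upper-quartile; per sample, zero-count exons against the
reference excluded; two-sided trims of 30% on M-values and 5% on
A-values; inverse asymptotic-variance weights; factors rescaled to a
unit geometric mean. The test suite pins this to the reference
implementation to 1e-10 on random matrices.

## The NB GLM engine

Each exon g gets a log-link negative-binomial GLM with offsets
`log(lib_size * factor)` and variance `mu + phi * mu^2`. One-way
layouts — which include every design this package builds (intercept
plus one group indicator) — factorize into independent per-group
intercept fits, solved by vectorized Fisher scoring across all exons
at once; arbitrary full-rank designs fall back to per-exon IRLS
(convergence when the coefficient step falls below 1e-8, at most 50
iterations, non-convergence flagged per exon, never fatal). With
`phi = 0` the fit is exactly Poisson, which the tests exploit against
an independent `glm()` oracle. All-zero exons get near-zero fitted
means, zero deviance, and are excluded from testing (reported as
skipped).

Dispersion estimation maximizes the Cox–Reid adjusted profile
likelihood (APL): the NB log-likelihood at the constrained fit minus
`0.5 * log det(X' W X)`, which removes the downward bias of plugging
in fitted means. Three layers:

* **common** — one `phi` maximizing the summed APL, searched on a
  15-point log grid over [1e-4, 4] and refined by golden-section on
  log-phi (tolerance 1e-3);
* **trended** — exons binned by average log2-CPM (about 100 per
  bin), per-bin common dispersions smoothed by first-degree loess of
  log-dispersion on abundance (span 0.5). Fewer than 10 bins fall
  back to linear interpolation, one bin or degenerate abundance to a
  flat trend; predictions are clamped to [1e-6, 10];
* **tagwise** — per exon, the maximizer of
  `APL_g(phi) - 0.5 * prior_df * (log phi - log trend_g)^2`,
  i.e. a weighted likelihood with a normal prior on log-dispersion
  centered at the trend. The objective is evaluated on a 25-point
  grid with quadratic interpolation around the maximum. `prior_df`
  defaults to 10; an infinite `prior_df` returns the trend exactly,
  which is also the explicit code path. This quadratic-penalty form
  was chosen over sharing a smoothed APL across neighbors because it
  makes the shrinkage limit exact and keeps the estimate strictly
  between the exon's own maximizer and the trend.

## The two tests and the consensus

The **LRT** fits full and intercept-only models at the tagwise
dispersions and refers the deviance difference to chi-square with one
degree of freedom. The **QLF** fits at the trended dispersions, forms
the quasi-dispersion `s2_g = deviance / residual df`, squeezes it
toward its abundance trend with a prior df estimated by moment
matching of log scaled-F (the excess of `var(log s2)` over
`trigamma(df/2)` determines the prior df via the trigamma inverse),
and refers `F = (deviance difference) / s2_post` to
`F(1, residual df + prior df)`. This moment-matching squeeze is
simpler than the reference implementation's robustified fit; the test
suite cross-checks it against `limma::squeezeVar` (posterior
variances correlating > 0.99, prior df within a factor of 2.5 on
scaled-F draws). Reported log2 fold-changes come from a refit with a
0.125 prior count added to the counts — reporting only, never
inference — so they are always finite; the sign convention is
positive = over-represented in the comparison's first-named group.

BH-FDR is applied within each comparison and method independently; an
exon is a DPE when both tests pass FDR ≤ 0.001, and its direction is
the group favored by the LRT logFC. Consensus calling is strictly
more conservative than either test alone (a set intersection), which
the calibration suite confirms on simulated truth: the consensus
empirical FDR never exceeds either single test's.

## Exploration, classification, enrichment

"Normalized values" for clustering and ordination are TMM-adjusted
log2-CPM with prior count 0.5, restricted to the signature exons;
the source analysis never defines this matrix precisely, so the
choice is a documented interpretation, not a reproduction. Ward
clustering uses the D2 (squared-increment) variant by default with
`"ward.D"` available; PCA centers each exon, does not scale, and
fixes component signs so the largest-magnitude loading is positive.
U samples are *projected* into the PCA fitted on the compared groups
rather than refit, so the axes stay anchored to the cohorts being
contrasted. The MDS distance is the root-mean-square of the top-k
(default 500) largest absolute per-exon log2-CPM differences per
sample pair — the leading fold changes — followed by classical
metric MDS.

The classifier is a bagged-tree random forest written in compiled
code (no forest package exists in the supported environment): Gini
splits, bootstrap per tree, features subsampled per split, all
randomness drawn from R's RNG so a seed fixes the forest exactly.
`mtry = "all"` — the study's configuration of every signature exon
at every split — degrades the forest toward bagged trees; that is
faithful to the original setting and configurable. Evaluation is a
stratified 70/30 split (stratification protects the 17-sample M
class; the source is silent on it) repeated `n_repeats` times with
consecutive seeds; OOB error comes from each forest's out-of-bag
votes. U samples are assigned by the class probabilities averaged
over the repeat forests, with a near-tie flag when the top two mean
probabilities differ by less than 0.05 — those samples effectively
remain unassigned between the groups whose features they share.

Enrichment replaces the original web services (whose term databases
are version-bound and unreproducible) with a local one-sided
hypergeometric upper-tail test against user GMT files, BH-corrected
across sets; both raw and adjusted p-values are always reported. The
default universe is every gene of the filtered exon catalog, because
the original background was never stated; it is configurable.

## What the simulator states, and what a green test means

The generator's defaults are the study's stated world: 17 M, 68 N,
63 H, 11 U samples; log-normal library sizes around 3e7 fragments
(sdlog 0.3, matching ~100-200M read-pair exomes); baseline
abundances normal(4, 2) on log2-CPM truncated at 0; dispersion trend
`phi = 2/mu + 0.1`; planted effects of ±2 log2 units on 10% of
autosomal exons per comparison; 5% of exons on X/Y with presence
attenuated in one sex; U samples drawing each exon's mean from M or
N with probability one half (a per-exon mixture, not label noise, so
U lands geometrically between M and N in ordination). The default of
5000 exons is a desk-scale stand-in for the exome; the library size
is interpreted as the depth of the notional full assay, so the
simulated slice carries it explicitly rather than recomputing it
from column sums. Truth labels are derived from the constructed
group means, so an effect planted for one comparison that also
separates another is labelled truthfully in both.

The simulator draws independent NB counts. It does not emulate
GC/fragment-length bias, positional correlation along the genome,
batch structure, or contamination — so green calibration tests
establish that the statistics are correct under the NB model, not
that the pipeline is robust to artifacts real cfDNA carries.
The cohort-specific headline counts of the original study (1760 /
14,300 / 14,430 DPEs, the 510-exon signature, 382 genes, 35.9% OOB,
75% accuracy) depend on controlled-access patient data and are
context, not targets, for this package.

## Degenerate inputs and determinism

Zero-count exons are fitted at the numerical floor and skipped in
tests; zero library sizes are an error naming the sample; a
comparison with an empty group errors (and the full study skips it
with a warning, intersecting the remaining callsets); `top_k` larger
than the exon count is clipped with a warning; dispersion estimation
refuses designs with fewer than 2 residual df. All pipeline
randomness flows from one root seed through derived substreams, and
the full-study output set is byte-identical across reruns — enforced
by an acceptance test.

## Known limitations

* Designs are group-only; clinical covariates (age, sex) do not
  enter the GLM, matching the source analysis but limiting
  confounder control.
* The QL squeeze is not robustified against dispersion outliers.
* Chromosome-based sex-exon removal is coarser than a curated list.
* `mtry = "all"` reduces tree decorrelation; forests with smaller
  mtry usually classify better and are one flag away.
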