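---
title: "pfasmeta: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pfasmeta: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasmeta)
```

## The problem

Transcriptome-wide responses to per- and polyfluoroalkyl substances (PFAS)
have been measured in many species, tissues and platforms, but each
experiment is small and no single one can say which responses are
*conserved*. `pfasmeta` implements a meta-analytic pipeline that makes
heterogeneous exposure-vs-control contrasts commensurable and then asks,
per gene and per pathway, whether the response recurs across species.

The pipeline has six stages:

1. **Signatures.** Each contrast is summarized per gene as
   $s = -\log_{10}(p)\cdot \operatorname{sign}(\log \mathrm{FC})$ —
   positive for significant up-regulation, negative for significant
   down-regulation, magnitude proportional to significance.
2. **Ortholog mapping** of every species-level signature into a common
   reference (human-ortholog) gene space, via mapping tables or reciprocal
   best hits.
3. **Correlation.** Pairwise Pearson correlation of signatures over
   pairwise-complete genes, with t-distribution p-values.
4. **Integration.** Species-balanced weighted Stouffer combination of
   per-gene evidence, two-tailed normal p-values, Benjamini–Hochberg (BH)
   correction, and classification into conserved-response bands.
5. **Enrichment.** Permutation GSEA per contrast, then Stouffer
   integration of normalized enrichment scores (NES) across contrasts.
6. **Metabolite prediction.** Correlation sets learned from a paired
   transcriptome/metabolome reference, scored against each contrast
   signature, and integrated across contrasts.

## The signature and its Z-conversion

The signature depends on the DE engine only through the p-value and the
sign of the fold change. The built-in engine (`compute_differential_expression`)
is a moderated t-test on log2 library-size-normalized counts
(pseudocount 0.5), with per-gene pooled variances shrunk toward the mean
gene variance with a prior of 4 degrees of freedom and p-values from a t
distribution on `n1 + n2 - 2 + 4` degrees of freedom. This is deliberately
a *documented stand-in*: the method's contribution starts at the
signature, and externally produced DESeq2/limma tables drop in via
`read_de_table()`. p-values are floored at `1e-300`, capping $|s|$ at 300
without reordering significance; a zero fold change gives $s = 0$; genes
with missing p-values are dropped, not imputed.

For integration, signatures are converted to Z-scores by interpreting
$|s|$ as a two-tailed p-value on the $-\log_{10}$ scale:
$z = \operatorname{sign}(s)\,\Phi^{-1}(1 - 10^{-|s|}/2)$. Integrating raw
signatures is also available (`input = "signature"` in
`integrate_signature_matrix`), but z-conversion is the default because the
classification thresholds are expressed in normal-Z units with matching
two-tailed p-values (Z ≥ 10 ⇔ p ≤ 1.6e-23, Z ≥ 5 ⇔ p ≤ 5.8e-7; note these
printed correspondences are upper bounds, i.e. the exact values
1.524e-23 and 5.733e-7 rounded *up* at two significant figures).

## Species balance and integration

With contrast counts per species as uneven as 55 vs 4, unweighted
integration would be dominated by the best-sampled species. Each contrast
therefore receives weight $1/n_{\text{species}}$, giving every species
equal total weight, and genes are combined as
$Z = \sum w_i z_i / \sqrt{\sum w_i^2}$ over the contrasts where the gene
is present. The $\sqrt{\sum w_i^2}$ denominator is the standard weighted
Stouffer form and keeps $Z$ standard-normal under the null; note that
duplicating a species' contrasts leaves each species' weighted *numerator*
contribution unchanged but does change the denominator normalization —
that is a property of the weighted form, not a bug, and is asserted
explicitly in the test suite.

Genes enter integration only if present in at least `min_species`
(default 6) distinct species; the filter is applied *before* integration
and before BH correction (one family over all retained genes). Whether the
original analysis filtered before or after integration is not stated
anywhere we could verify; filter-first is the more conservative family
definition. The cross-contrast standard deviation used for classification
is computed on the *signature* scale (the scale of the published banding),
with missing entries excluded. Classification bands (defaults
`z_hi = 10`, `z_lo = 5`, `sd_cut = 10`): high-SD bands are evaluated
first, so a gene with `Z = 12, sd = 15` is `up_high_sd` while
`Z = 12, sd = 5` is `up_consistent`; genes with `z_lo <= |Z| < z_hi` but
high SD remain `none`.

## Ortholog mapping choices

"Most likely ortholog" is implemented as the highest-confidence target per
source gene (ties: lexicographically smallest target). When several source
genes collapse onto one reference gene, the retained signature is the one
with maximum $|s|$ (ties toward the more positive value). The original
work does not print its collapse rule; max-|s| preserves the strongest
evidence and matches the role extreme signatures play downstream, and
`collapse = "mean"` is available for sensitivity analysis. Two-hop
conversions (e.g. fish species mapped via zebrafish) compose two tables
with the *minimum* of the hop scores — a conservative confidence. For
reciprocal best hits the default e-value cutoff is `1e-5` (unstated in the
source; a conventional BLAST threshold), best = maximum bit score with
ties broken by minimum e-value then subject id.

## GSEA implementation

Genes are ranked by signature descending (ties by gene id, for
determinism). The enrichment score is the weighted Kolmogorov–Smirnov
running-sum extremum with weight exponent 1 ($|s|$ weights). The null is a
*gene-label* permutation — random placements of the set's labels on the
ranked list — because the pipeline holds signatures, not expression
replicates; this is the scheme of the fast-GSEA family of algorithms.
Two refinements:

* when all $\binom{N}{k}$ placements number no more than `n_perm`, they
  are enumerated exhaustively, making small-universe p-values exact;
* sampled placements are drawn as antithetic mirror pairs (a position set
  and its reversal), which makes the null multiset exactly symmetric under
  reversal of the ranking. Consequently negating every signature negates
  every ES, NES, pathway Z and metabolite Z *exactly* (to IEEE summation
  order, ~1e-15), not just in distribution — provided the ranking is
  tie-free, which holds for continuous signatures.

`NES = ES / mean(|null ES| of the matching sign)`; `p` is the one-sided
permutation tail within the sign class, with the +1 correction. Sets with
fewer than `min_size = 5` genes in the signature (the "insufficient
pathway genes" rule) or more than `max_size = 500` are reported missing.
NES values are treated as approximately standard normal for Stouffer
integration across contrasts; this mirrors the original analysis and is an
approximation (the null NES distribution has unit *mean* by construction,
not unit variance) — integrated pathway p-values are calibrated in the
test suite empirically, not assumed.

## Metabolite prediction

The upstream method this stage follows is published only in outline, so
the implemented form is a faithful-in-spirit, fully documented stand-in:
per metabolite, Spearman correlations against all genes over the paired
reference samples; the top-`k` and bottom-`k` genes (default `k = 100`,
disjoint by construction) form positive and negative sets; a contrast's
prediction is `NES(positive) - NES(negative)` via the GSEA machinery
(positive = predicted increase); predictions are Stouffer-integrated
across contrasts and BH-corrected across metabolites. Spearman makes the
model invariant to monotone transforms of metabolite units. Counts are
first normalized by `vst_normalize()`: median-of-ratios size factors
(geometric-mean reference over genes with all-positive counts), rescaled
to median 1 — the rescaling only shifts the log output by a global
constant but makes the factors directly interpretable (a sample with all
counts doubled gets factor 2) — then `log2(count / sf + 1)`. The original
analysis ran this stage on human contrasts only; `run_pipeline()` exposes
`metabolite_species` for that restriction and defaults to all contrasts,
since synthetic studies have no distinguished reference species.

## What the synthetic world emulates — and what it does not

`generate_multispecies_study()` emulates the *shape* of the real corpus:
7 species with very uneven contrast counts (default 55, 20, 10, 9, 6, 6, 4
— 110 contrasts, human-dominated), ≥ 3 replicates per group, per-species
platforms of ~2000 genes with partial (90%) ortholog coverage, and a
planted, perfectly conserved core of 50 up- + 50 down-regulated genes at
|log2 FC| = 2. Counts are negative binomial (dispersion 0.1) with
gene-specific baselines drawn log-normally (meanlog 5, sdlog 1.5 — RNA-seq
like marginals), baselines shared across a species' contrasts. Tissue and
compound labels are carried as metadata but do not enter the generative
model: in the real data tissue effects are an observation, not a stated
model. Deliberately *not* modeled: dose–response and exposure-time
structure, batch and library-size artifacts, microarray intensity
distributions, partially conserved effects, and correlated genes. A green
recovery test therefore establishes that the pipeline recovers a conserved
signal planted under its own assumptions — it does not validate the
biology of any real-data gene list, which is why reproducing the published
65-gene list is explicitly out of scope.

The null-calibration check (no planted genes; integrated p approximately
uniform by Kolmogorov–Smirnov) is run at 2000 genes and 10 contrasts
spread over 5 species with 5 replicates per group and full ortholog
coverage, so that every gene is testable; the species count for this check
is not pinned down by any stated value and 5 × 2 is the smallest balanced
layout with multiple species.

## Numerical conventions

* p-value floor `1e-300` (so $|s| \le 300$, $|z| \lesssim 37$);
  `z_to_p()` uses the normal survival tail and does not underflow before
  $|Z| \approx 37$.
* BH is the explicit step-up construction, cross-checked against
  `stats::p.adjust` in the tests.
* Correlations with fewer than `min_overlap = 100` shared genes are
  suppressed rather than reported (unstated upstream; 100 genes keeps the
  t-approximation and the correlation estimate stable); `|r| = 1` is
  flagged degenerate with p reported as 0.
* All randomness flows through per-call seeds (`with_rng`), which save and
  restore the global RNG state: same configuration + seed ⇒ byte-identical
  serialized outputs.
* Pipeline configs are R lists / JSON documents (no YAML dependency); the
  run manifest records the seed and an md5 parameter hash.

## Known limitations

The built-in DE engine is not DESeq2/limma and its p-values are only
approximately calibrated for strongly non-normal, low-count genes (the
moderated-t on log counts is slightly conservative; the KS null check
passes but not by a wide margin). NES normality for Stouffer integration
is an approximation inherited from the upstream design. The metabolite
module's set-based form is one of several plausible readings of the cited
method and is exposed as a configurable strategy rather than a claim about
the original implementation.
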