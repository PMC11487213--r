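---
title: "Phenotypic comorbidity networks from discharge diagnoses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic comorbidity networks from discharge diagnoses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pcnet analyzes comorbidity patterns in hospital cohorts defined by a thyroid
disease (TD) indication — a discharge diagnosis of `C73` (thyroid cancer, TC)
or `E00`–`E07` (benign thyroid disease, BTD) — from long-format ICD-10
diagnosis tables. This vignette documents the statistical model behind each
stage, the tunable parameters, the synthetic-cohort generator used to
validate the pipeline, and the design decisions that were genuinely open.

## Analysis unit and cohort cleaning

Each hospitalization record is treated as an independent observation: a
patient readmitted in a different health state contributes a separate
record. A record is an encounter id, an age in whole years, a sex, and a
*set* of 3-character ICD-10 category codes (subcodes are truncated, so
`E04.1` and `E04.9` both count once as `E04`).

`filter_cohort()` applies four rules, in a fixed order, each logged with
before/after counts:

1. keep adults (age ≥ 18) with at least one TD code;
2. drop codes from ICD-10 chapters XV–XXII (leading letters `O`–`Z`:
   pregnancy and childbirth, perinatal and congenital conditions, symptom
   codes, injuries, external causes, and health-status factors — these
   describe circumstances rather than comorbid diseases);
3. drop records left with fewer than `min_codes = 2` codes (a record with
   only its TD indication carries no co-occurrence information);
4. drop rare diseases with prevalence below `min_prevalence = 0.02` in the
   cleaned cohort.

The code-count rule deliberately runs *after* the chapter exclusion, so a
record whose only non-TD code is a symptom code is removed. The rare-disease
rule has two defensible readings — overall prevalence, or prevalence within
every declared subgroup. Both are implemented (`subgroups` argument of
`filter_cohort()`); overall is the default. The rule is a point-estimate
threshold on the crude prevalence; no test-based variant is applied.

The *comorbidity universe* is the set of surviving codes minus the whole TD
block (`C73`, `E00`–`E07`): TD codes stay out of comorbidity prevalence
tables, but remain available as network nodes (`include_td = TRUE`, the
default) because the TD–comorbidity links are themselves of interest.

## Prevalence, subgroup differences, enrichment

Prevalence is `n/N` with a 95% Wald interval `p ± 1.96·sqrt(p(1−p)/N)`
clamped to [0, 1]. The Wald form is the package default because it
reproduces the interval arithmetic used in the published tables this
package's reporting style follows; a Wilson interval is available
(`method = "wilson"`) and preferable for small `n`.

Two subgroups are contrasted with the relative difference

> d = (P_a − P_b) / [(P_a + P_b)/2],

a symmetric, scale-free quantity in [−2, 2], together with a pooled
two-proportion z-test (two-sided, no continuity correction). A comorbidity
is *different* when |d| > 0.1 and the z-test is significant at α = 0.05, and
*enriched* in the higher-prevalence subgroup when additionally the
prevalence ratio is ≥ 1.5 (a "≥ 0.5-fold increase"). The ratio reading of
the fold rule is the default; an alternative reading on the
relative-difference scale (|d| ≥ 0.5) is exposed as
`fold_as_relative_difference` because the phrase is genuinely ambiguous.
No multiple-testing correction is applied by default, matching the common
descriptive use of such tables; Benjamini–Hochberg is one argument away
(`p_adjust = "BH"`) and clearly labeled in the output.

Age structure uses five bins (18–39, 40–49, 50–59, 60–69, ≥ 70). Trends are
Spearman correlations of the per-bin prevalence (or mean comorbidity count)
against the bin *ordinal* — ranks, not midpoints, so the result is invariant
to bin-width choices; constant profiles are reported as rho = 0 rather than
`NA`. Age-profile clustering is K-means on the raw, unscaled 5-vectors:
scaling is deliberately omitted because prevalence *magnitude* is the
clinically meaningful separator (a very common disease with a steep age
gradient should not be co-clustered with a rare one of similar shape).
K-means runs with 50 random restarts under a fixed seed; when `k` is not
given it is chosen by the elbow criterion — the largest second difference of
the within-cluster sum of squares over k = 1…10.

## The comorbidity network

For diseases a and b with marginal record counts `n_a`, `n_b` and joint
count `n_ab` in a cohort of `N` records:

- **cosine index** `C_ab = n_ab / sqrt(n_a n_b)` — the co-occurrence
  strength used as edge weight; it discounts prevalence, so a link between
  two rare diseases that almost always coincide scores as high as one
  between two common ones;
- **phi coefficient** `r_ab = (N n_ab − n_a n_b) / sqrt(n_a n_b (N−n_a)
  (N−n_b))` — the Pearson correlation of the two 0/1 indicator vectors;
- **significance** via `t = r sqrt((N−2)/(1−r²))` on N−2 degrees of freedom,
  two-tailed.

The cosine index has no natural significance scale, so the edge cutoff is
*calibrated against the Pearson count*: with K the number of pairs with
positive, significant phi, the cutoff is the K-th largest cosine value, and
the network keeps the pairs at or above it. Only positive correlations count
toward K — the cosine is nonnegative and the edges represent coexistence,
not avoidance. Ties at the cutoff are all included (inclusive policy,
flagged when it broadens the edge set), so the edge count equals K up to
ties; this identity is asserted in the test suite on every synthetic run.
Two-tailed p-values on the positive-only count are used; this choice is
configurable via `alpha` and documented rather than guessed differently.
Pairs where either disease is absent from a subgroup are skipped, not
zero-filled; K = 0 yields an explicitly empty network (infinite cutoff).

`pcn()` returns the fitted network as a classed object carrying the node
table (with prevalence), the edge table (counts, cosine, phi, t, p), the
full pair table, the calibration, and an igraph graph; `print()`,
`summary()` and `plot()` methods give the usual modelling-object surface.

## Network metrics and subgroup comparison

Structural metrics are computed on the unweighted thresholded graph:
density `2E/(N(N−1))`, per-node degree, average neighbor degree, and
*unnormalized* betweenness centrality (raw shortest-path counts — values
well above 1 are expected and match how such tables are usually printed).
Mean degree `2E/N` is reported alongside the degree median/IQR because
summary tables in this literature sometimes print one under the other's
name; the package labels both explicitly.

Node importance uses weighted PageRank (damping 0.85, the standard default;
convergence handled by igraph): each undirected edge acts as two directed
edges with transition probability proportional to the cosine weight, and
isolated nodes teleport uniformly. The top-5 list is the headline output;
ties are broken lexicographically and flagged. `remove_top_nodes()`
implements the hub-knockout experiment, reporting the share of edges lost
when the highest-degree (or highest-betweenness, or named) nodes are
removed.

Two subgroup networks are compared edgewise by `abundant_connections()`:
an edge is *abundant* in a subgroup when it is unique to that subgroup's
network, or present in both with a cosine weight at least 0.05 higher
(threshold configurable); everything else is shared.

## The synthetic-cohort generator

Restricted clinical data cannot ship with the package, so every stage is
validated against `simulate_cohort()`, whose ground truth is known exactly:

- ages are truncated-normal (default mean 58, SD 14 on [18, 95], matching a
  median near 58 with IQR roughly 49–67 as seen in tertiary-hospital TD
  inpatients); sex is Bernoulli with a configurable female share (default
  0.6, reflecting the female predominance of TD admissions);
- every record draws exactly one TD indication from `td_mix` (default
  goiter-dominant, ~6.5% thyroid cancer);
- comorbidity i enters a record via a logistic model:
  `logit P = logit(p_i) + s_i·[male] + a_i·(age−18)/10` — one parameter per
  effect reproduces monotone age gradients and sex enrichment;
- pairwise co-occurrence is planted through a shared latent Bernoulli
  factor per pair: the latent rate s solves
  `P(ab) = p_a + p_b − 1 + (1−p_a)(1−p_b)/(1−s) = c·sqrt(p_a p_b)` for the
  target cosine c (solved by `uniroot` to 1e-12), while base rates are
  deflated so marginals are preserved. The closed form is exact even when a
  disease participates in several planted pairs, which is what makes
  planted-hub experiments possible. Targets at or below the independence
  cosine `sqrt(p_a p_b)` reduce to independence; targets above
  `sqrt(min(p)/max(p))` are rejected as infeasible at configuration time,
  naming the pair.

The generator is a deterministic function of its configuration, including
the seed: one seeded RNG stream with fully vectorized draws, so identical
configurations give byte-identical cohorts.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: records carry exactly one TD code (real records
can carry several); with sex or age effects present, the latent-rate
calibration uses the base prevalences, so planted cosines are exact in
expectation only for effect-free diseases; diseases share no unplanted
dependence beyond what sex/age confounding induces; and there are no coding
artifacts (up/under-coding, laterality duplicates) or temporal structure.

## Problem sizes and numerical choices

The bundled `paper_like_config()` uses ~55 comorbidities with prevalences
2–35% and eight planted cardiometabolic pairs. Test and validation runs use
2,000–20,000 records and a 50,000-record run for marginal-convergence
checks — sizes at which binomial sampling error (3-SE bands) is small enough
to make the assertions meaningful while a full suite run stays fast.
Monte-Carlo tolerances throughout are 3 standard errors (binomial or
bootstrap with 200 resamples). K-means determinism comes from a fixed seed
plus 50 restarts; PageRank and betweenness inherit igraph's tolerances
(PageRank scores are checked to sum to 1 within 1e-9).

## Known limitations

Cross-sectional co-occurrence only: no temporality, no direction, no
causal reading. Three-character truncation merges heterogeneous subcodes.
The ICD-9 bridge is only as good as the user-supplied map, and dotless
four-character `E`-subcodes are ambiguous between ICD-9 and ICD-10 shapes
(the dotted form disambiguates). The Wald interval degrades near 0 and 1 —
use Wilson there. Records with unknown sex are kept overall but silently
excluded from sex strata.
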