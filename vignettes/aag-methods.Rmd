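---
title: "Attribute association graphs: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribute association graphs: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aagraph)
```

## The model

An attribute association graph (AAG) summarises a case-control cohort
table as a directed graph over *attributes*. The method deliberately
uses only conditional and unconditional frequencies — no distributional
assumptions, no fitted parameters — so that every number on the graph
has a direct clinical reading, and so that high-dimensional tables and
missing values are handled gracefully: each node depends only on one
variable, each edge only on one ordered pair of variables.

**Cohort split.** Participants are partitioned by *any-of* inclusion
criteria: anyone satisfying at least one criterion (on a non-missing
value) is in the disease group, everyone else in the control group. A
participant missing *all* criterion variables therefore lands in the
control group. This is a documented choice, not a neutral fact: the
control group is defined by the absence of findings, and the partition
must be total. If non-ignorable missingness on inclusion variables is
plausible, exclude such participants upstream.

**Attributes.** Categorical and binary variables contribute one
attribute per category value. Metric variables are discretized into
`low` / `normal` / `high` bands around a *reference range* computed on
the pooled data set (both groups): all values within one standard
deviation around the mean, with the sample SD (n − 1 denominator). Two
readings were genuinely open and are fixed here as: (1) "within SD"
means mean ± 1·SD, with no multiplier; (2) `normal` is the closed
interval [lower, upper], with strictly-outside values mapping to `low`
and `high` — clinical out-of-range attributes are conventionally written
with strict inequalities (e.g. "> 1.2 mg/dL"). With SD = 0 all
non-missing values are `normal`; the empty `low`/`high` nodes still
exist and are typically removed by filtering. Data-driven ranges can be
overridden per variable with clinical reference intervals
(`apply_overrides()`); overridden ranges are flagged
`manual_override` and exported with the node.

**Node statistics.** Per group $i \in \{d, c\}$ with group size $g_i$,
valid count $n_i$ and member count $c_i$: the relative total share
$c_i/g_i$, the relative attribute share $p_i = c_i/n_i$ (the
missing-value adjustment — missing participants leave the denominator),
the difference $\delta = |p_d - p_c|$ and the quotient
$\gamma = \max(p_d,p_c)/\min(p_d,p_c)$. Always
$c_i/g_i \le p_i$, with equality exactly when the group has no missing
value for the variable. Under missingness completely at random, $p_i$
is an unbiased estimate of the underlying attribute probability while
the total share shrinks by the observation rate — this is what the
synthetic-data tests verify.

**Labels.** With $p = \max(p_d, p_c)$: *highly frequent* ($p \ge 0.5$),
*frequent* ($0.1 \le p < 0.5$), *infrequent* ($p < 0.1$). Distinction:
*highly related / highly inverse* when $\delta \ge 0.2$ or
$\gamma \ge 2.0$; *related / inverse* when ($\delta \ge 0.1$ or
$\gamma \ge 1.5$) and below the strong band; *unrelated* otherwise.
All thresholds sit in `aag_config()` and default to these standard
constants; the boundary cases are closed from below (a value exactly at
a threshold takes the stronger label).

**Edges.** For an ordered pair of attributes from *different* variables
(same-variable pairs are excluded by default: bands of one variable are
mutually exclusive, so their edges are degenerate $q = 0$ statements),
the conditional share $q_i = o_i / c_i^x$ is compared with the target's
unconditional share: $\delta'_i = q_i - p_i^y$ (signed; conditioning can
*suppress* the target) and $\gamma'_i = q_i / p_i^y$. Edge types reuse
the 0.2/2.0 and 0.1/1.5 thresholds.

## Decisions where the standard rules are incomplete

Three aspects of edge typing are not fully specified anywhere and are
this package's own choices, all configurable:

* **Sign handling** (`signed_edge_magnitude`, default `TRUE`): types are
  driven by the magnitude pair $(|\delta'|,\ \max(\gamma', 1/\gamma'))$,
  so a strongly suppressive relation ($q$ far *below* $p^y$) is
  highlighted as strongly as an enhancing one. Setting it to `FALSE`
  restricts attention to positive effects.
* **Group aggregation** (`edge_aggregation`, default `"max"`): the
  stronger group decides the type, mirroring how the frequency label
  uses the maximum share; `"disease"` / `"control"` restrict to one
  group.
* **Zero shares**: $\gamma$ (and $\gamma'$) with a zero denominator and
  positive numerator is treated as $\infty$, i.e. exceeding every
  quotient threshold; with both shares zero it is 1 (equal). Ties
  $p_d = p_c$ are *unrelated* with direction `equal`. Small-count
  artifacts from this rule are the main reason the default filter
  requires 10 participants per node and edge.

## Filtering

The full graph is quadratic in the number of attributes and mostly
noise at the periphery. `filter_aag()` prunes it with explicit rules —
minimum per-group count (`min_abs_count = 10`), minimum maximum share
(`min_max_share = 0.01`), dropping low-type edges
(`keep_low_edges = FALSE`) and low co-occurrence edges
(`min_cooccurrence = 10`), plus white/blacklists. **These defaults are
this package's own, non-authorial choices** — the AAG method prescribes
that nodes and edges are filtered by their statistical parameters but
fixes no concrete rules; ours were chosen once to suppress unstable
small-count ratios. Filtering only ever removes elements and never
recomputes statistics, so the result is a true subgraph; tightening any
single rule is monotone.

## Dashboard preparation

Histograms round each value to the nearest multiple of a bin width from
{0.1, 0.5, 1, 5, 10, 50}, chosen per group from the SD. The SD-to-width
mapping has no canonical definition and is fixed here as *the largest
admissible width not exceeding SD/3* (floored at 0.1), which targets at
least ~6 bins across ±1 SD. Rounding of exact midpoints is half away
from zero, for determinism across platforms. Bins with fewer than 3
participants or less than 0.5% of the group are *summarized*: their
counts are merged into the nearest retained bin on the side toward the
distribution centre (ties resolved toward the centre), and the number of
merged participants is reported as `summarized_count`; retention is
decided once on the original counts, not iteratively. Whether
"summarized" should mean merging, pooling into an "other" bin, or
dropping is an open choice; merging keeps the count conservation
`sum(retained counts) == n_valid` that the exports rely on. A
distribution with no qualifying bin at all is flagged `removed`.
Normalized group averages divide each variable's three group means
(disease, control, all) by their maximum. Conditional bin averages use
pairwise-complete participants of the chosen group, bin the first
variable by the same rules, and average the second variable within each
retained bin.

## Correlation companion

`pearson_ci()` computes Pearson's r on pairwise-complete pairs and a
one-tailed confidence bound via the Fisher transformation
($z = \operatorname{atanh} r$, $SE = 1/\sqrt{n-3}$), with the p-value
from the normal tail of $z/SE$ — consistent with the CI construction; no
t-based alternative is offered. The *side* defaults to the sign of the
point estimate, matching the reporting style "the CI lies fully above /
below 0". Note the statistical consequence: with a data-chosen side, a
true null is excluded in ~10% of samples, not 5%. The coverage test in
the acceptance suite therefore fixes `side = "greater"`, for which the
5% one-sided error rate is exact (up to the Fisher approximation).
Degenerate inputs (zero variance, |r| = 1) are flagged rather than
silently propagated. `attribute_group_correlation()` encodes attribute
and disease membership as 0/1 indicators over participants with valid
attribute values — a point-biserial/phi-type check that a node's
direction agrees with standard inference.

## The synthetic cohort generator

`simulate_cohort()` produces tables with analytically known ground
truth: per-group category probabilities for binary/categorical
variables, per-group normal distributions for metric variables,
missingness completely at random (MCAR) injected after value generation,
and a dedicated `group` indicator referenced by the emitted cohort spec.
`plant_conditional()` regenerates a binary target conditional on a
binary source with the stated per-group conditional probability while
preserving the target's marginal, so expected edge statistics are closed
form ($\delta' = q - t$, $\gamma' = q/t$).

What it emulates: the variable mix (laboratory-style metric values,
questionnaire-style categories), group-dependent prevalence and
missingness rates. What it does **not** emulate: skewed or multimodal
metric distributions, missingness that depends on values (MNAR), and
correlation structure beyond explicitly planted pairs. A green recovery
test therefore establishes that the pipeline recovers *planted* effects
under MCAR — not that real cohort data satisfy those assumptions. The
MCAR restriction is deliberate: the valid-count denominator of $p_i$ is
exactly the MCAR correction, so MCAR is the regime in which the method's
missing-data claim is well-defined.

Sizes used in the test suite follow the stated conditions where they
exist (5,000 per group for parameter recovery and MCAR checks; 10,000
replicates of n = 200 for CI coverage; 100 cohorts within the
2,000 × 30 caps for oracle equivalence); remaining sizes were chosen
once for runtime and are not tuned to outcomes — the oracle check is
exact equality, so cohort size does not affect its stringency.

## Numerical choices

* All shares are kept at full double precision internally; rounding (4
  significant digits) happens only in the human-readable CSV exports.
  JSON and GraphML serialize doubles with 17 significant digits
  (`%.17g`), which is sufficient to reproduce the exact double on
  import; infinite quotients are encoded as the string `"Inf"` since
  JSON has no infinity literal.
* List-valued export properties are ordered control group first, disease
  group second, with the disease group named `posGroup` and the control
  group `negGroup`.
* Reference ranges need at least 2 non-missing values; variables below
  that are skipped with a warning. Nodes whose valid count is zero in a
  group get `NA` shares and are excluded from labeling; edges undefined
  in both groups are dropped with a warning.

## Limitations

The AAG is a data-exploration device, not an inference procedure: its
thresholds are conventions, marginal and pairwise frequencies cannot
detect higher-order structure, temporal data are out of scope, and only
two groups are compared. Confidence intervals are provided as a
companion check, not built into the labels, and no multiple-testing
correction is applied.
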