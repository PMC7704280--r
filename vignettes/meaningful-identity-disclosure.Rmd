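---
title: "Measuring meaningful identity disclosure risk in fully synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meaningful identity disclosure risk in fully synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthrisk)
```

## The risk model

`synthrisk` measures whether sharing a fully synthetic sample `S`,
generated from a real sample `R` drawn from a population `P`, could
let an adversary (i) correctly map a synthetic record to a real
person and (ii) learn correct new sensitive information about them.
Both must happen for a disclosure to be *meaningful*: a match that
teaches the adversary nothing, or a lesson attached to the wrong
person, is not a privacy harm in this model.

Matching runs purely on equality of quasi-identifier tuples. There is
deliberately no record-linkage scoring: with fully synthetic data
there is no correct record-level mapping to score, only the binary
fact that an identical tuple exists (`I_s`). Adversary imperfection is
handled separately by the λ adjustment rather than by fuzzy matching.

For each real record `s`, with `f_s` and `F_s` the equivalence-class
sizes in the sample and population, the two attack directions are

$$A = \frac{1}{N}\sum_s \lambda_{c,s}\,\frac{1}{f_s}\,I_s R_s,
\qquad
B = \frac{1}{n}\sum_s \lambda_{c,s}\,\frac{1}{F_s}\,I_s R_s,$$

and the reported risk is $\max(A, B)$: the custodian does not know
which direction the adversary will try, and assumes one attempt.
Because $f_s \le F_s$ and $n \le N$, the population-to-sample
direction is weakly smaller — random sampling itself protects — and
the test suite asserts this ordering on every fixture.

Assumptions worth stating explicitly:

* the real sample is a subset of the supplied population on the
  quasi-identifiers (violations are an error, not silently patched);
* the adversary's background knowledge is error-free — only the data
  carry errors, which is the conservative direction;
* population class sizes `F_s` are computed exactly from a supplied
  population table (or user-supplied per-class counts). Estimating
  `1/F` from the sample alone is a different problem and out of scope
  here.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.09 | acceptability bound on the overall risk; the value used by large health-data custodians for public release. A report exactly at the threshold is acceptable (the threshold is the boundary of acceptability). |
| `L` | 5 (%) | minimum share of applicable sensitive variables that must be learned for a match to count; `>= L` (a record at exactly L% counts). |
| `error_rate` | (0, 0.0426, 0.0852) | triangular (min, mode, max) for the per-variable data error rate; the mode is the weighted mean error rate reported for health databases. |
| `verification_rate` | (0, 0.23, 0.46) | triangular (min, mode, max) for the probability a suspected match can be verified, centred on the rate observed in published re-identification attacks. |
| `correlation` | 0.3 | magnitude of the (negative) rank correlation between the two rates: errors depress verification. 0.3 is a medium effect size. |
| `mad_multiplier` | 1.48 | scales the MAD in the continuous learned test to one Gaussian standard deviation; adjustable because the one-SD choice is a (conservative) judgement call. |
| `kmeans_max_k` | 10 | ceiling for the cluster-count selection. |

The literature gives the central values of the two rates but not
their ranges. The shipped ranges are symmetric about the cited value
and clipped to [0, 1] — which also dissolves any ambiguity between
"mode" and "mean" readings of the cited values, since a symmetric
triangular has both equal. Users with better information should
override the triples; asymmetric triples are interpreted as
(min, mode, max).

## The λ adjustment

A suspected match succeeds only if none of the `k` active
quasi-identifier values carries an error, $(1-e)^k$, and the match
can then be verified, $v$: $\lambda_s = v_s (1-e_s)^k$. One $(e, v)$
pair is drawn per real record through a Gaussian copula over the two
triangular marginals: correlated standard normals (Pearson
$\rho = 2\sin(\pi\rho_S/6)$ for the target Spearman $\rho_S = -0.3$)
are pushed through `pnorm` and the closed-form triangular inverse
CDFs, so the marginals are exact and the rank correlation is
controlled. To keep the adjustment from over-attenuating the risk,
the model uses the midpoint with the maximum,
$\lambda_c = (\lambda_s + 1)/2 \in (0.5, 1]$.

During the attack search the same per-record $(e, v)$ draws are
re-scored at each configuration's `k`. This is a deliberate choice:
re-drawing per configuration would let the maximization harvest
sampling noise, making the argmax unstable across runs. With shared
draws the search is deterministic given the seed.

## Learning something new

Nominal/binary variables: value `j` with real-sample proportion
`p_j` has distance `d_j = 1 − p_j`; a matched equal pair is learned
when `d_j` exceeds one Bernoulli standard deviation,
$(1-p_j) > \sqrt{p_j(1-p_j)}$, which simplifies algebraically to
`p_j < 1/2` (the suite checks the equivalence on a grid). Binary
variables are treated exactly as nominal ones.

Continuous variables: values are discretized with univariate k-means
so a record gets a cluster proportion `p_s`, and a pair is learned
when $p_s\,|X_s - Y_t| < 1.48\,\mathrm{MAD}$, with the MAD unscaled
(the 1.48 lives in the explicit multiplier). Note the continuous
distance weight is `p_s` itself, not a `1 − p` complement — a small,
tight cluster (low `p_s`) makes the inequality easier to satisfy,
i.e. outliers are easier to learn about, mirroring the nominal
logic's direction.

The cluster count is chosen by majority vote over four indices —
average silhouette, Calinski–Harabasz, Davies–Bouldin, and the
within-SS elbow (largest second difference) — over
`k = 2..min(10, #distinct)`, ties toward smaller `k`. Larger index
panels exist; four well-understood indices keep the selection
reproducible and dependency-free, and the panel is the natural
extension point. k-means itself is a deterministic 1-D Lloyd
iteration seeded at evenly spaced quantiles (an emptied cluster is
reseeded at the farthest point), so discretization needs no RNG
state. For very long columns the index panel is evaluated on a
deterministic 1500-point thinning; the final clustering always uses
all values.

Aggregation: for each matched synthetic partner, the fraction of
applicable sensitive variables learned is compared against `L`%;
`R_s = 1` if **any** partner reaches it. `R_s` is computed only where
`I_s = 1` (elsewhere the term is zero regardless, and the test suite
confirms compute-then-mask equivalence).

## Degenerate inputs and missing values

* **Missing quasi-identifier values never match anything** — each
  such record forms a singleton class. Since its `I_s` is then 0,
  its `F_s` is set to 1 rather than looked up (the sentinel tuple
  cannot occur in the population); the record contributes zero risk
  either way, which is the non-fabricating choice.
* **Missing sensitive values** are skipped: they leave both the
  learned count and the applicable-variable denominator.
* **Zero applicable sensitive variables** (none declared, or all
  missing): the model degrades to pure identity disclosure,
  `R_s = 1`, with a warning. Conservative by construction.
* **Continuous quasi-identifiers** must be binned through a hierarchy
  level before matching; raw floating-point equality is refused as a
  usage error rather than silently producing near-zero match rates.
* **Degenerate triangular ranges** (min = mode = max) yield
  deterministic draws — useful for forcing `λ_c = 1` in validation.
* **Real and synthetic samples of different sizes** are accepted; the
  formulas only index real records, and `I_s` does not care how many
  synthetic records exist. No reweighting is attempted.

## The attack search

An adversary can match on any non-empty subset of the
quasi-identifiers at any generalization level. Risk is **not**
monotone in the subset — dropping a QI raises match chances (`I_s`)
but also inflates class sizes (`f_s`, `F_s`) — so no pruning bound is
sound and the search is exhaustive, capped (default 10,000
configurations, an error suggesting the cap or shallower hierarchies
when exceeded). Generalization, by contrast, is provably monotone on
`f`, `F` and `I` individually, which the property suite exercises.
Sensitive variables are never generalized: after a match the
adversary reads them at real-sample granularity.

Hierarchies ship for the common health quasi-identifier shapes (age
bands, date truncation, ZIP prefixes, suppression) and are otherwise
user-defined; levels must strictly coarsen, which is validated
against the observed values.

## The synthesizer

`synth_fit()` implements sequential synthesis: for sequence
A→E→C→B→D, fit E ~ A, C ~ A+E, B ~ A+E+C, D ~ A+E+C+B; generation
samples A′ from the empirical marginal and each later variable by
routing the partial synthetic record down its tree and sampling
uniformly from the terminal node's training values. Values are
therefore always observed training values (synthetic categories are
a subset of real ones), and `min_leaf` is the privacy dial: leaves of
size 1 on distinctive data can reproduce training rows nearly
verbatim, and the integration suite asserts that growing the minimum
leaf size lowers the measured risk.

The trees are deviance-split binary partitions (the `tree` package)
with `min_leaf` and `mindev` as stopping rules; conditional-inference
stopping would be an equally valid choice — the contract is the
partition-and-sample-from-node behaviour, not a particular split
statistic. The default sequence is the column order; choosing a
better sequence is left to the user. Inherited limitation: a
categorical predictor may have at most 32 levels inside a tree fit
(a position whose fit fails degrades to its root node, i.e. marginal
resampling of that variable). Unseen predictor categories at routing
time are mapped to the training-modal category; this cannot occur
when the generator's own output feeds the predictors.

## What the fixtures emulate — and what they do not

`generate_population()` builds populations with controlled
uniqueness (forced class counts, all-unique identifiers), skewed
categorical frequencies, Gaussian-mixture continuous variables and
simple conditional-table dependence; `sample_real()` draws the
10–20%-style sample; `control_synthetics()` provides the three
degenerate synthesizers (copy / permute / independent) whose risk
ordering is known a priori and asserted over 20 seeds. The worked
example reproduces the package's 8-person illustration exactly.

Passing on these fixtures shows the machinery is correct: the
matcher against a nested-loop oracle, the engine against a
straight-line transcription of the sums (at 1e−12 on 50 random
fixtures of up to 500 records), the sampler against closed-form
CDFs at 10^5 draws, the orderings the model implies. It does **not**
show that any particular real dataset's risk is low: real data has
far higher quasi-identifier cardinality, missingness patterns, and
dependence structure than these generators produce, and headline
numbers for restricted external datasets are not reproducible from
fixtures. The acceptance script's pipeline demonstration uses a
2,000-person population with a 10% sample — big enough to exercise
every code path, small enough to run in seconds.

## Known limitations

* Cross-sectional data only; no longitudinal/event-level support.
* No confidence intervals on the risk: the model reports point
  values; sampling variability of the λ draws can be explored by
  re-seeding.
* No adversary cost model or plausibility weighting across attack
  configurations; the maximum is taken.
* Population class sizes must be supplied (table or counts), not
  estimated.
* No semantic weighting of sensitive variables — each applicable
  variable counts equally toward the L% rule.
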