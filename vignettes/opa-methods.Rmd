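---
title: "The Ordinal Priority Approach: model, solvers, and synthetic test bench"
author: "opamcdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Ordinal Priority Approach: model, solvers, and synthetic test bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opamcdm)
```

## The decision problem

Group multi-attribute decision making asks a panel of experts to select among
discrete alternatives evaluated on several attributes. Many elicitation
schemes demand cardinal input — scores, ratio judgments, pairwise comparison
matrices — which experts outside quantitative fields find hard to provide
consistently. The Ordinal Priority Approach (OPA) asks only for **orders**:
a priority order over the experts themselves, each expert's importance order
over the attributes, and each expert's preference order over the
alternatives under each attribute. The motivating application in this
package is the appraisal of four digital at-home rehabilitation platforms by
a nine-member panel of end-users/caregivers, therapists and developers on
six attributes; its panel, catalogue and published expert weights ship as
the `phyxio_*()` fixture family.

## Model and assumptions

With expert priority rank $i \in \{1,\dots,p\}$, attribute rank $j$ assigned
by that expert, and alternative rank $r \in \{1,\dots,m\}$ under that
attribute, OPA solves

$$\max Z \quad \text{s.t.}\quad
Z \le i\,j\,r\,(W^{(r)}_{ijk} - W^{(r+1)}_{ijk}),\qquad
Z \le i\,j\,m\,W^{(m)}_{ijk},\qquad
\sum W_{ijk} = 1,\ W \ge 0 .$$

The multipliers are **rank positions, not identities**: a judgment made by a
lower-priority expert, or about a lower-priority attribute, must clear a
proportionally larger hurdle to contribute the same weight gap. Maximizing
the minimum scaled gap $Z$ produces the flattest weight profile the ordinal
information permits; the optimum always has $Z > 0$ and all three marginal
sums (experts, attributes, alternatives) equal to one. The model assumes the
elicited orders are the experts' true opinions and that the $1/(i j r)$
harmonic profile is an acceptable cardinalization of "rank"; it produces no
uncertainty quantification.

## Two solution paths

`opa()` exposes both paths and `solver = "auto"` picks between them.

**Simplex LP.** `build_lp()` emits one weight variable per (expert, ranked
attribute, alternative) plus $Z$, one inequality row per distinct rank
position of every (expert, attribute) chain, and the normalization equality;
`solve_opa_lp()` hands the system to `boot::simplex()`. Rows are written in
`A1 x <= b1` form. Variable order is fixed (expert rank, then the expert's
attribute rank, then alternative rank) so repeated runs are bit-identical on
one platform.

**Closed form.** For complete strict instances all constraints are tight at
the optimum, giving
$$W^{(r)}_{ij} = \frac{Z}{ij}\sum_{s=r}^{m}\frac1s,\qquad
Z = \Big(m\sum_i\sum_j \tfrac{1}{ij}\Big)^{-1}.$$
The derivation is elementary: for fixed $Z$ the chain constraints give
pointwise-minimal weights by back-substitution, the total of those minima is
proportional to $Z$, and the normalization pins it down; since any slack
could only inflate the total above one, the tight solution is the optimum.
Two consequences are worth noting. First, $\sum_{r=1}^m\sum_{s=r}^m 1/s = m$
(each $1/s$ appears $s$ times), so an expert's marginal weight collapses to
$(1/i)/H_p$ **regardless of how they ranked attributes and alternatives** —
this invariance is what lets the package reproduce the published expert
table even though the underlying rankings were never deposited, and it is
asserted as a property test. Second, attribute marginals are proportional to
$1/j$ within each expert, which fixes the expert-by-attribute significance
matrix up to the rank assignment.

The two paths are developed independently and their agreement (max-abs
difference across random instances) is a standing test; the suite requires
$\le 10^{-8}$, observed agreement is at machine precision.

## Ties, missing attributes, tie-breaks

* **Ties** are encoded densely (1, 1, 2 — never 1, 1, 3), which keeps the
  telescoping chain well-defined over distinct rank positions. In the LP a
  tie group occupies one chain position, represented by its first member in
  catalogue order, with equality rows binding the members' weights.
  Competition-style ranks are rejected at parse time.
* **Missing attributes** (an expert declined or could not rank one) are
  represented by absence; the expert's remaining attribute ranks are
  compacted to $1,\dots,n_i$. The alternative — imputing a worst rank — was
  rejected because it fabricates preference information. Documented
  consequence: with missing data the expert marginals deviate from the
  $(1/i)/H_p$ profile.
* **Tied expert profiles** receive a shared dense rank (flagged with a
  warning); the shared rank is the $i$ multiplier.
* **Reported ranks** tie when weights agree within the solver tolerance
  ($10^{-8}$ by default); display order inside a tie follows the catalogue,
  and report tables round half-up to 4 decimals while `report.json` keeps
  full precision.

## Expert prioritization

`rank_experts()` orders profiles lexicographically over role, professional
position, experience bracket and education, each an ordinal scale with the
best level first (`opa_scales()`). Role dominance (end-user/caregiver ≻
therapist ≻ developer) reflects the application: the recipients of the
technology carry the most weight. Strict lexicographic comparison is the
simplest rule consistent with all nine published ranks in the case study,
and is adopted; position is compared before experience, experience by
bracket lower bound, and the education scale is a conventional attainment
ordering that is never actually reached as a tie-breaker on the fixture
panel, so any reasonable attainment order reproduces the published ranking.
Category matching tolerates case, dash and parenthetical variants of the
printed labels.

## Synthetic test bench

Real elicitation data beyond the fixture panel are unavailable, so
`gen_instance()` defines the test-bench statistics explicitly:

* **Rank noise** follows the Mallows model, the Kendall-distance exponential
  family $P(\pi) \propto e^{-\theta\, d_K(\pi,\pi_0)}$, sampled exactly by
  repeated insertion (`rmallows()`). $\theta = 0$ is uniform over
  permutations; $\theta \approx 2$ gives visibly noisy but correlated
  panels; $\theta \ge 20$ is effectively degenerate at the reference. It is
  the standard ordinal-noise model with a tractable exact sampler; no claim
  is made that the real experts followed it.
* **Ties** are injected by merging each adjacent rank boundary with
  probability `tie_prob` after sampling, preserving the underlying order.
* **Missingness** drops each attribute independently with probability
  `missing_prob`, never below one attribute per expert.
* **Profiles** are sampled uniformly over the scale levels; expert ranks are
  a uniform random permutation by default (`expert_rank_mode = "random"`),
  keeping generated instances complete-strict so the closed form applies,
  or derived from the sampled profiles (`"profile"`), which may tie.
* Everything is reproducible from the spec seed.

What passing tests on this bench shows: the solver pipeline is correct under
controlled ordinal noise, ties and missingness, and consensus is always
recovered. What it does not show: anything about the behaviour of real
expert panels — correlated judgment errors, strategic ranking, attribute
dependence — none of which the generator emulates.

## Problem sizes and numerical choices

The test suite and the acceptance script run the fixture scale
($9 \times 6 \times 4$, 217 LP variables, solved in well under a second),
100 random complete strict instances with $p, n, m \le 6$ for the dual-route
comparison, 25 consensus panels and 200 noisy panels at $\theta = 2$ for
recovery — sizes chosen so the whole battery reruns in seconds while still
exercising every structural regime (degenerate $1\times1\times1$, all-tied,
heavily missing). The LP tolerance is $10^{-8}$; normalization is checked to
$10^{-9}$ after every solve. Recovery at $\theta = 2$ with nine experts and
six attributes is essentially perfect (observed fraction ≥ 0.99 across
seeds), far above the $1/24$ chance rate for four alternatives.

## Known limitations

* Tables of attribute and alternative weights for the case study cannot be
  checked numerically — only structurally — because the per-expert rankings
  behind them were never published; reconstructing them is an
  underdetermined inverse problem the package deliberately does not attempt.
* No fuzzy, grey or robust OPA extensions; no cardinal input variants.
* `boot::simplex` is a dense tableau implementation; it is comfortable at
  panel scales (hundreds of variables) but not intended for instances orders
  of magnitude larger.
* Leave-one-expert-out re-ranks the remaining panel densely and re-solves;
  it reports ranking changes, not confidence statements.
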