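---
title: "Valuing and selecting interventions for a health benefits package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing and selecting interventions for a health benefits package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbpdesign)
```

## The model

A health benefits package (HBP) is the set of interventions a health system
commits to funding. Including an intervention commits money that would
otherwise have funded other care, so its value must be judged net of that
*health opportunity cost*. The package's single behavioural parameter is

* **k** — the marginal cost at which the system averts one DALY with its
  existing portfolio, in USD per DALY. Spending $c$ dollars anywhere
  displaces $c/k$ DALYs averted elsewhere. The default, $61/DALY, is an
  empirical estimate for Malawi; 1x and 3x GDP-per-capita norms ($372,
  $1116) are carried as comparison scenarios. `k` enters every metric
  linearly, so all results are easy to re-derive under a different estimate.

Each intervention $i$ is described by its ICER $r_i$ (USD per DALY averted,
undefined for cost-saving interventions), eligible annual caseload, total
cost $C_i$ and total DALYs averted $E_i$ at full implementation, and the
observed implementation level $\ell_i \in [0,1]$. Costs and effects are
assumed to scale linearly with coverage (constant returns): at level $\ell$
the intervention costs $\ell C_i$ and averts $\ell E_i$ DALYs. Nonlinear
coverage-effect curves are out of scope; with them, every "value of moving"
quantity below would become a path integral rather than a difference.

The two metrics of value are

$$\text{net DALYs}_i(\ell) = \ell E_i - \frac{\ell C_i}{k}, \qquad
  \text{financial value}_i(\ell) = k \cdot \text{net DALYs}_i(\ell).$$

A cost-saving intervention has $C_i < 0$, so the second term *adds* health:
the savings fund other care. Net DALYs are positive exactly when
$r_i < k$ for records whose cost, effect and ICER are mutually consistent
($C_i = r_i E_i$) — a property the synthetic generator guarantees by
construction and the test suite checks exactly.

## Package selection

`hbp_select()` includes every cost-saving intervention plus every
intervention with $r_i \le k$: with no binding budget constraint this is the
net-health-maximising set (each member contributes non-negative net DALYs,
each excluded intervention would contribute negative net DALYs), and the
test suite confirms it against exhaustive subset enumeration on small
synthetic sets. The budget is an *output* — the total full-implementation
cost of the included set — which is what makes the choice of `k` a
deliberation about affordability.

Interventions are indivisible: bars on the frontier are included whole, and
no fractional inclusion of the marginal intervention is attempted, matching
how published league tables account. `select_budget()` provides the
complementary budget-capped problem for expansion and donor analyses. Its
default greedy rule (cost-savers and forced inclusions first, then
ascending-ICER fill, stopping at the first candidate that does not fit) is
a lower bound on attainable net health — with indivisible interventions the
knapsack optimum can differ — which suits its use here: quantities derived
from it ("minimum health opportunity cost") are conservative. An exact
enumeration method (`method = "exact"`, practical to ~20 interventions) is
available and is what the property tests compare against.

Ordering ties: published league tables print ICERs rounded to the dollar,
which collides genuinely distinct ratios. `rank_by_icer()` therefore
honours a published `icer_rank` column as the first tie-break when present
(as in the Malawi transcription), falling back to name then id so every
ordering is deterministic.

## Scale-up, expansion, donor conditions

`scaleup_report()` aggregates, over the package, the spending gap
$\sum_i (1-\ell_i) C_i$ and the system-strengthening potential
$\sum_i (1-\ell_i) E_i$ — the most health that policies relaxing
implementation constraints could add. Per intervention, the financial value
of moving to full implementation is also a budget ceiling: the most that
could be spent removing that intervention's constraints while remaining
cost-effective. Aggregates default to the threshold package rather than all
analysed interventions, since the gap is a property of what the system has
committed to fund; callers can pass any explicit package.

`expand_package()` appraises the rival use of the gap: funding
beyond-threshold interventions. Additions are credited at their *observed*
implementation levels — newly added interventions face the same delivery
constraints as existing ones — with a `level = "full"` sensitivity switch.
Every addition has $r_i > k$, so expansion never raises total net health;
`breakeven_fraction()` expresses the comparison as the share of the
strengthening potential that implementation efforts would need to realise
to beat expansion.

`conditionality_cost()` quantifies donor conditionalities (and equally any
non-health objective pursued via forced inclusion or exclusion): the
difference in total net DALYs between the unconstrained health-maximising
package at a budget and the best package honouring the constraints, also
expressed in money at `k`. With the greedy fill this is a conservative
(minimum) estimate; no multi-criteria weighting scheme is implemented —
the quantified health trade-off is the deliverable.

## The Malawi worked example

`malawi_interventions()` transcribes the published Malawi league tables:
67 interventions, ICERs from cost-saving to $1646/DALY, implementation
levels 1%–100% (mean 46%). Published cost/caseload columns are in $1000s
and DALY columns in 1000s; the loader converts to raw units. Two
transcription decisions matter:

* The schistosomiasis row uses the source's higher-precision worked-example
  values (cost $76,527; 23,754 DALYs) in place of the rounded table cells.
* The published *net*-DALY and financial-value columns are **not**
  reproducible from the printed cost and DALY columns at k = $61 (the
  source's internal cost basis is unprinted; e.g. 23,754 − 76,527/61 =
  22,499, not the printed 12,562). They are therefore carried as reference
  columns (`*_printed`) and never recomputed; "value of moving" checks are
  full − actual differences of those printed components. For the same
  reason the printed DALY totals and ICER columns are not mutually
  consistent row by row; selection uses the ICERs, aggregates use the DALY
  columns, and the two are never mixed.
* The top-ranked cotrimoxazole row is internally ambiguous in the source
  (marked cost saving yet showing a positive total cost) and is flagged
  `low_confidence`; it is excluded from exact-value tests.

```{r malawi}
iv <- malawi_interventions()
econ <- economy_params(61, c(A = 61, B = 372, C = 1116))

pkg <- hbp_select(iv, econ, "A")
pkg

rep <- scaleup_report(iv, econ, pkg)
rep

expand_package(iv, econ, pkg)
```

At k = $61 the 48 most cost-effective interventions form a package costing
about $265M a year at full implementation. Closing the ~$198M gap between
that and actual spend could avert up to ~38M additional DALYs, whereas
spending the same gap on the 19 beyond-threshold interventions adds only
~2.7M — about 7% of the strengthening potential, which is the break-even
share implementation efforts would have to achieve.

## Synthetic data

`simulate_interventions()` draws self-consistent records emulating the
empirical spread of the Malawi tables: ICERs log-uniform on $1–$2000
(straddling all three thresholds), caseloads log-uniform on 10^3^–10^7^,
DALYs per case log-uniform on 0.005–30 (the fixture's range runs from mass
media's ~0.01 to obstructed labour's ~27), implementation Beta(2,2)
(mean 0.5, full support on (0,1), matching the observed 46% mean and
1–100% range), and a 2% chance of a cost-saving intervention (1 of 67 in
the fixture). Because `cost = ICER × DALYs-per-case × cases` by
construction, the sign rule and selection optimality hold exactly — which
is precisely what makes the generator a fair test bed for the algebra and
an unfair one for data-quality robustness: real league tables carry
rounded, unit-mixed and internally inconsistent cells (the fixture
preserves several), and passing tests on synthetic data says nothing about
such defects beyond what the fixture tests cover. Correlated disease
programmes and complementarities between interventions are deliberately
not simulated.

Default sizes keep everything desk-scale: property tests enumerate subsets
only up to ~14 interventions (2^14 masks), and generated sets of 30–200
rows exercise the vectorised paths; the full suite runs in seconds.

## Numerical choices and limitations

* All internal arithmetic is in raw USD and raw DALYs at double precision;
  only reporting layers round. Equality checks in selection use exact
  comparisons on ICERs (`r <= k`), not tolerances, since ICERs are data,
  not computed quantities.
* Ties at exactly `r = k` contribute zero net health; they are included by
  `hbp_select()` (the boundary is "can afford to pay up to k") and their
  inclusion is optimum-indifferent.
* `metric_delta()` matches rows by id and subtracts exactly; additivity of
  package aggregates over per-intervention deltas is asserted, not assumed.
* The break-even fraction is undefined for zero strengthening potential and
  is signalled as an error rather than returned as NaN.
* Donor analyses measure only the modelled constraint; constraints that
  make other interventions harder to implement would raise the true cost
  above the reported minimum.
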