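# hbpdesign

Tools for designing health benefits packages (HBPs) — the explicit set of
interventions a health system commits to funding — on the principle of
health opportunity cost. Ministries of health in low-income settings must
choose among far more interventions than their budgets can deliver;
cost-effectiveness ratios alone cannot guide that choice because they
ignore the scale of each intervention's eligible population and the health
forgone elsewhere when money is committed.

## The metrics

Given an intervention with total cost *C* and total DALYs averted *E* at
full implementation, and a health system whose marginal productivity is *k*
dollars per DALY averted (every dollar spent displaces 1/*k* DALYs averted
elsewhere):

- **Net DALYs averted** = *E* − *C*/*k* — health gained minus health
  forgone. For a cost-saving intervention (*C* < 0) the savings *add*
  health.
- **Financial value to the healthcare system** = *k* × net DALYs — the
  extra budget other services would need to produce the same net health.

Both scale linearly with the implementation level (the fraction of the
eligible population actually reached). On top of them the package builds:

| Question | Function |
|---|---|
| What scale of package can the system afford? | `hbp_select()`, `budget_at_thresholds()`, `frontier_table()` |
| Which interventions are "best buys"? | `league_table()` |
| What is scaling up implementation worth? | `scaleup_report()`, `rank_by_scaleup_value()` |
| Expand the package or invest in implementation? | `expand_package()`, `breakeven_fraction()` |
| What do donor conditions cost in health? | `conditionality_cost()`, `evaluate_matched_funding()` |

The Malawi essential-health-package league tables ship as a worked example
(`malawi_interventions()`); `simulate_interventions()` generates synthetic
intervention sets for testing.

## Worked example

```r
library(hbpdesign)
iv   <- malawi_interventions()
econ <- economy_params(61, c(A = 61, B = 372, C = 1116))

hbp_select(iv, econ, "A")
#> Health benefits package
#>   threshold: $61 per DALY averted (scenario A)
#>   interventions included: 48
#>   budget (full implementation): $264,529,527
#>   total DALYs averted (full implementation): 49,448,754
#>   total net DALYs averted: 45,112,204

scaleup_report(iv, econ)
#> Scale-up report
#>   package: 48 interventions
#>   spending gap (full - actual): $197,825,878
#>   DALYs averted, full implementation:   49,448,754
#>   DALYs averted, actual implementation: 11,429,188
#>   system-strengthening potential:       38,019,566 DALYs

expand_package(iv, econ)
#> Package-expansion report
#>   additions evaluated at actual implementation
#>   gap available: $197,825,878; spent on additions: $59,621,580
#>   interventions added: 19
#>   DALYs averted by additions: 2,738,780
#>   total DALYs with expansion: 14,167,968
#>   forgone vs implementation route: 35,280,786 DALYs
#>   break-even fraction: 7.2%
```

Reading: at Malawi's estimated health opportunity cost of $61 per DALY
averted, the 48 most cost-effective interventions form a package costing
~$265M/year fully implemented. Because observed coverage averages 46%,
~$198M of that is not currently being spent; investing it in
implementation could avert up to ~38M more DALYs, whereas spending it on
the 19 interventions beyond the threshold would avert only ~2.7M —
implementation efforts need to achieve just 7% of their potential to be
the better buy.

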