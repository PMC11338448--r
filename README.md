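# wmwties

Two-sample Wilcoxon-Mann-Whitney (WMW) tests with explicit, honest handling
of tied observations — and a simulation engine that quantifies what tie
handling costs in type-I error and power.

Ties are ubiquitous in measured data: instruments round, detection limits
truncate, scores are discrete. Because rounding piles observations up where
the density is high, ties are *not* an evenly spread subsample — omitting
them reshapes the sample and can break the very assumptions a rank test
relies on. This package is for biostatisticians and applied researchers who
want to (a) run a WMW test whose p-value is exact *with ties present*, and
(b) see, by simulation, why omitting ties is a bad idea even though it does
not inflate the type-I error.

## The statistic and the tests

For groups of sizes \(n_1, n_2\) (\(N = n_1 + n_2\)), each tied set of
pooled values receives its **mid-rank** (the average of the integer ranks
it occupies) and the test statistic is the rank sum of group 1,
\(W = \sum_{i=1}^{n_1} R_i\). Three p-value engines share this statistic:

* **Exact permutation** (`method = "exact"`): the full conditional null
  distribution of \(W\) over all \(\binom{N}{n_1}\) label assignments,
  computed without enumeration by a dynamic-programming *shift algorithm*
  over doubled mid-ranks (doubling makes every achievable rank sum an
  integer, so counts are exact). One-sided p-values are exact tail
  probabilities; the two-sided p-value is
  \(P(|W^* - EW| \ge |w - EW|)\) with \(EW = n_1(N+1)/2\).
* **Monte-Carlo permutation** (`method = "montecarlo"`): `B` random
  relabelings with the add-one estimator \((b+1)/(B+1)\), for sample sizes
  beyond exact enumeration.
* **Asymptotic** (`method = "asymptotic"`): the normal approximation with
  the tie-corrected variance
  \(\mathrm{Var}(W) = \frac{n_1 n_2}{12}\bigl[(N+1) -
  \sum_j (t_j^3 - t_j) / (N(N-1))\bigr]\)
  and (by default) a continuity correction.

Two tie policies: `ties = "include"` keeps the complete data with
mid-ranks; `ties = "omit"` first removes every observation whose value
occurs more than once in the pooled sample (the practice the simulation
study argues against). If omission empties a group, an error of class
`"wmw_empty_group"` is raised — there is no test to report.

## Worked example

```r
library(wmwties)
x <- c(2.1, 2.4, 2.4, 3.0, 3.1, 3.1)   # e.g. control, measured to 0.1
y <- c(2.4, 3.1, 3.6, 3.8, 4.0, 4.6)   # treated
wmw_test(x, y, method = "exact")
#> 	Exact permutation Wilcoxon-Mann-Whitney test
#> W = 26, p-value = 0.04545
#> ties: include (n1 used = 6, n2 used = 6, omitted = 0)

wmw_test(x, y, method = "exact", ties = "omit")
#> 	Exact permutation Wilcoxon-Mann-Whitney test after omission of tied observations
#> W = 3, p-value = 0.1333
#> ties: omit (n1 used = 2, n2 used = 4, omitted = 6)
```

With all 12 observations and mid-ranks, group 1's rank sum (W = 26) is
small enough that only 4.5% of the 924 equally likely relabelings are as
extreme: significant at 5%. Omitting the six tied observations leaves 6 of
12 values and the evidence evaporates (p = 0.13) — the cost of discarding
real data.

The same comparison at scale, one cell of the simulation study
(exponential data, location shift 1, rounding to 1 decimal):

```r
sc <- wmw_scenario("exponential", shift = 1, n1 = 10, n2 = 10, decimals = 1)
run_scenario(sc, reps = 2000, seed = 1)
#> Scenario: exponential, shift 1, n1 = 10, n2 = 10, 1 decimal(s), alpha = 0.05/0.01
#>   2000 replicates; mean pooled size after omission 11.2; 4 emptied-group replicates
#>      method  policy alpha rejections n_performed      rate
#>       exact include  0.05       1452        2000 0.7260000
#>       exact include  0.01        934        2000 0.4670000
#>  asymptotic include  0.05       1421        2000 0.7105000
#>  asymptotic include  0.01        846        2000 0.4230000
#>       exact    omit  0.05        740        1996 0.3707415
#>       exact    omit  0.01        245        1996 0.1227455
#>  asymptotic    omit  0.05        697        1996 0.3491984
#>  asymptotic    omit  0.01        152        1996 0.0761523
```

Omission halves the power (0.73 → 0.37 at the 5% level) and on average
throws away almost half the sample (20 → 11.2 observations); in 4 of 2000
replicates it left a group empty and no test could be run at all.
`run_study(default_study_grid(), ...)` runs the full 64-cell grid
(4 distributions × 4 shifts × 2 designs × 2 rounding precisions) and
`build_table()` / `write_results()` assemble the report tables.

A thin command-line wrapper (`inst/cli/wmw.R`) exposes `test`, `simulate`,
and `version` subcommands; see its header for flags.

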