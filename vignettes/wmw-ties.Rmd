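---
title: "Tied observations in the Wilcoxon-Mann-Whitney test: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tied observations in the Wilcoxon-Mann-Whitney test: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmwties)
```

## The problem

The two-sample Wilcoxon-Mann-Whitney (WMW) test compares groups through the
rank sum \(W\) of group 1 in the pooled ranking. Real measurements are
rounded — by instruments, detection limits, or reporting conventions — and
rounding continuous values creates ties wherever the underlying density is
high. Two ways of coping are in circulation: keep everything and use
mid-ranks, or delete every tied observation before testing. The second
option sounds tidy but is statistically costly: the deleted observations
are not a random subsample, so the reduced data may no longer represent the
population, and a large fraction of the information can vanish. This
package implements both policies around three p-value engines and a
simulation study that measures the consequences.

## The tests

**Mid-ranks.** Each set of \(t\) equal pooled values receives the average
of the \(t\) consecutive integer ranks it occupies. Rank sums then satisfy
\(W_1 + W_2 = N(N+1)/2\) identically, and the permutation mean of \(W\) is
\(EW = n_1(N+1)/2\) regardless of the tie pattern.

**Exact permutation test.** Conditional on the observed pooled values, all
\(\binom{N}{n_1}\) assignments of labels are equally likely under the null.
The null distribution of \(W\) is computed by a shift-algorithm dynamic
programme: mid-ranks are doubled (making every mid-rank, hence every rank
sum, an integer), and a table of counts indexed by (number of ranks chosen,
partial doubled sum) is updated one pooled rank at a time. The final slice
at \(n_1\) chosen ranks gives the count for every achievable value of
\(2W\). Counts are integers held in doubles, which is exact up to
\(2^{53}\); `rank_sum_distribution()` refuses beyond that
(\(N \approx 55\) balanced) and points to the Monte-Carlo engine, which is
the right tool long before that size. p-values are ratios of these exact
counts.

**Tail conventions.** One-sided p-values are the exact tails
\(P(W^* \le w)\) / \(P(W^* \ge w)\). The two-sided p-value is defined as
\(P(|W^* - EW| \ge |w - EW|)\), both tails at the observed distance from
the permutation mean — the standard permutation-test convention, and
identical to doubling a tail when the null distribution is symmetric
(always true without ties). With ties the distribution need not be
symmetric (pooled values \(\{0, 0, 1\}\), \(n_1 = 2\): support
\(\{3, 4.5\}\) with counts 1 and 2), and the conventions genuinely diverge.
We keep the distance convention throughout; it makes the two-sided p-value
an exact statistic of the distribution ("how much probability lies at
least this far from the centre") and gives the level guarantee below with
no case analysis.

Because all comparisons happen on the integer lattice of doubled rank
sums, no floating-point tolerance enters any tail computation.

**Binary data and Fisher's exact test.** With only two distinct pooled
values the conditional distribution of \(W\) is a linear image of the
hypergeometric distribution of the 2×2 table, so the exact WMW test *is*
Fisher's exact test: one-sided p-values agree with `fisher.test` to the
last digit (verified over all tables with margins up to 8). For the
two-sided test, `fisher.test` uses a different tail-ordering convention
(summing all tables whose probability does not exceed the observed one);
on asymmetric tables that convention and the distance convention can
differ — both are legitimate two-sided readings of the same exact test.
The test suite verifies the two-sided agreement against an independent
hypergeometric enumeration under the common convention.

**Level guarantee.** For any threshold \(\alpha\), the two-sided p-value
satisfies \(P(p \le \alpha) \le \alpha\) *exactly* under the permutation
null: \(p\) is a monotone function of the distance \(|W - EW|\), so
\(P(p \le p_v) = p_v\) for every achievable value \(p_v\). The suite
checks this analytically from the computed distribution, not by
simulation. Rejection downstream uses the strict rule \(p < \alpha\),
which keeps the guarantee with room to spare.

**Monte-Carlo test.** \(B\) uniform random relabelings; the add-one
estimator \(p = (b+1)/(B+1)\) counts the observed statistic as one of its
own permutations, so \(p > 0\) always and the test stays valid at any
\(B\). Default \(B = 10^4\), standard error at most
\(1/(2\sqrt{B}) = 0.005\).

**Asymptotic test.** \(z = (W - EW \mp 0.5)/\sqrt{\mathrm{Var}(W)}\) with
the tie-corrected variance
\(\frac{n_1 n_2}{12}[(N+1) - \sum_j (t_j^3 - t_j)/(N(N-1))]\), referred to
the standard normal. The continuity correction of 0.5 toward the mean is
on by default, matching `stats::wilcox.test` (the suite verifies exact
agreement with it, with and without correction); `correct = FALSE` turns
it off. If every pooled value is tied the variance is zero; the test
returns \(p = 1\) with a warning instead of dividing by zero, the same
answer the (degenerate) exact distribution gives.

## Tie policies

`ties = "include"` is the identity. `ties = "omit"` removes every
observation whose value occurs at least twice in the *pooled* sample —
within-group ties included, since a tie is a property of the pooled data,
not of group membership. This pooled reading is also the only one
consistent with the simulation outcome that 1-decimal exponential samples
of 20 collapse to about 9 observations on average. Omission is idempotent
and leaves an all-distinct pool, so the two policies coincide on the
reduced data. When omission empties a group, `wmw_test` signals an error
of class `"wmw_empty_group"` rather than inventing a p-value; the
simulation engine counts these replicates separately.

Rounding (`round_values`) uses base R's round-half-to-even. Exact halves
have probability zero for continuous draws, so this choice cannot affect
simulated results; it is simply the ambient convention of the environment
the simulations run in.

## The synthetic-data generator

`draw_dataset` emulates a location-shift design with rounding-induced
ties: group 1 is drawn i.i.d. from one of four unit-scale base
distributions — normal (variance 1), exponential (rate 1), Cauchy
(scale 1), Laplace (scale 1) — group 2 from the same distribution shifted
by \(\Delta \in \{0, 0.5, 1, 1.5\}\), and *both* groups are then rounded
to \(d \in \{1, 2\}\) decimals. The shift is applied before rounding
because rounding models the instrument, which observes shifted values. The
shift goes to group 2 by convention; with two-sided tests and these
designs the choice is immaterial. The Laplace sampler uses the inverse
CDF; the Cauchy "shift" offsets the location parameter (the distribution
has no mean). Scale differences, mixture contamination, and
fixed-percentage tie injection are deliberately out of scope: the point of
the generator is that the *number and placement* of ties emerge from the
density and the rounding, varying across replicates as they do in
practice.

What passing tests on these data do **not** show: behaviour under unequal
variances, dependent observations, ordinal scales with few levels, or
detection-limit censoring (a one-sided pile-up quite unlike symmetric
rounding).

## The simulation study

`run_scenario` draws `reps` datasets from a scenario and applies four
variants per dataset: exact and asymptotic tests, each with ties included
and after omission, all two-sided. Rejection rates divide the number of
p-values strictly below \(\alpha\) by the number of *performed* tests:
replicates where omission empties a group are excluded from the omit-test
denominators and reported as `empty_group_count`. The mean pooled size
after omission averages over *all* replicates (an emptied group
contributes its actual reduced count); with that reading the reproduced
mean sizes match the reference values directly, so no alternative
denominator is offered. The Monte-Carlo engine is exercised by unit tests
but is not a table variant — at these sample sizes the exact test is
available, and the tables compare it with its asymptotic approximation.

The replicated grid (`default_study_grid`) is 4 distributions × 4 shifts ×
2 designs (balanced 10/10, unbalanced 14/7) × 2 rounding precisions, at
levels 5% and 1%, 10000 replicates per cell in the full study.
Determinism: each scenario gets a derived seed
(master + 1000003·index, mod \(2^{31}-1\)) and runs on its own RNG
stream, so results are independent of grid order and each cell is
reproducible in isolation. Within a scenario the exact null distribution
is memoised on the doubled mid-rank multiset — replicates with the same
tie pattern share one shift-algorithm run — which makes the 10000-replicate
cells run in seconds.

Problem sizes: the packaged test suite runs its property layer at
\(n_1, n_2 \le 7\) with full brute-force enumeration as the oracle, and
its simulation layer at 2000 replicates per scenario (binomial SE
\(\le 0.011\); tolerances 0.035 on proportions, 0.3 on mean sizes).
`scripts/acceptance.R` runs the headline scenarios at the full 10000
replicates. Reproduction of reference rejection rates is statistical —
within binomial noise — not bitwise, since the original study's seed is
unknown.

One open choice the tables cannot settle: whether the asymptotic variant
in the reference results used a continuity correction. The default here
(`correct = TRUE`, as in `stats::wilcox.test`) is slightly conservative at
these sample sizes; all replicated *exact*-test cells are unaffected.

## Known limitations

* Exact counts require \(\binom{N}{n_1} \le 2^{53}\); beyond that use the
  Monte-Carlo engine (statistically indistinguishable at such sizes).
* Two groups only; no confidence intervals for the location shift, no
  signed-rank or stratified variants.
* The omit policy is implemented faithfully in order to be studied — the
  simulation results are an argument against using it.
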