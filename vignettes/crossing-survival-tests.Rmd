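---
title: "Testing for survival differences under crossing hazards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for survival differences under crossing hazards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossurv)
```

## Why more than the log-rank test

For two right-censored arms the log-rank test sums, over the pooled
distinct event times $t_1 < \dots < t_k$, the observed-minus-expected
event counts of one arm,

$$Z = \sum_i w(t_i)\left(d_{i1} - n_{i1}\frac{d_i}{n_i}\right),
\qquad
V = \sum_i w(t_i)^2\,
\frac{n_{i1} n_{i2} d_i (n_i - d_i)}{n_i^2 (n_i - 1)},$$

with $w \equiv 1$, and refers $T^2 = Z^2/V$ to $\chi^2_1$. Its power
is concentrated in the proportional-hazards (PH) direction: when one
arm's hazard is uniformly a constant multiple of the other's, nothing
beats it. When the hazards — and hence the survival curves — *cross*,
early positive and late negative score increments cancel and the
log-rank statistic can sit near zero for arbitrarily large true
differences. `crossurv` implements eleven tests spanning the standard
answers to this problem, all consuming the same `(time, status,
group)` records and all reproducible from a single seed.

This vignette documents the models, the defaults and the design
decisions; every number quoted here is recomputed by the test suite
or by `scripts/acceptance.R`, not copied from elsewhere.

## The battery

**Weighted log-rank family** (`logrank_test()`, `peto_peto_test()`,
`wlr_test()`). The weight acts on the pooled Kaplan–Meier left limit
$\hat S(t-)$: Fleming–Harrington $G(\rho,\gamma)$ weights
$\hat S(t-)^\rho (1-\hat S(t-))^\gamma$ stress early
($\rho>0$), late ($\gamma>0$) or middle differences; the Peto–Peto
test uses $w = \hat S(t-)$ itself. Using the *left* limit keeps the
first event's weight well defined for $\gamma > 0$. Variance terms at
times with $n_i = 1$ are set to zero (the $n_i - 1$ denominator). Two
conventions worth stating: ties between events and censorings at the
same time are resolved events-first (the censored subject stays in
that risk set), and the Peto-Peto weight defaults to the plain pooled
left-limit KM — the $n/(n+1)$-modified estimator is available via
`peto_weight(modified = TRUE)` since the literature uses both and
reports rarely say which.

**Combination tests.** `mdir_test()` stacks several weighted scores
into $S = Z^\top \hat\Sigma^+ Z$ (spectral pseudo-inverse, singular
values below $10^{-10}$ of the largest treated as zero), so the test
has power in the span of its weights; the default pair is the
constant weight plus the crossing direction $1 - 2\hat S(t-)$, which
changes sign near the pooled median. Its p-value is a label
permutation tail with the finite-sample correction
$(1 + \#\{S^\pi \ge S\})/(1 + B)$ — the correction is why a
resampled p-value is never exactly zero. `maxcombo_test()` takes the
maximum of the standardized FH(0,0), FH(0,1), FH(1,0), FH(1,1)
statistics; the four-element grid is the conventional choice and is
configurable. Its default p-value is the multivariate-normal tail
$1 - P(\max_a |G_a| \le M)$ under the estimated score correlation,
evaluated by seeded Monte-Carlo integration (default $10^5$ draws,
exact in dimension one); redundant weights (zero variance, perfect
correlation) are reduced away first rather than jittered. For fewer
than about 30 subjects per arm the permutation method is the better
choice and is provided.

**RMST tests.** The restricted mean survival time
$\mu(\tau) = \int_0^\tau S$ is estimated by exact step-function
integration of the KM curve, with variance
$\sum_{t_i \le \tau} A_i^2 d_i/(n_i(n_i - d_i))$,
$A_i = \int_{t_i}^\tau \hat S$. `rmst2_test()` refers
$(\hat\mu_1 - \hat\mu_2)/\sqrt{V_1 + V_2}$ to the normal law;
`rmst1_test()` uses the same statistic with a label-permutation
p-value, which is exact under the strong null of equal distributions
— permutation was chosen over bootstrap or perturbation resampling
for exactly that property. The default truncation follows the rule
$\tau = 0.9\min(\max_j t_{1j}, \max_j t_{2j})$ (90% of the smaller
arm-wise maximum observed time); $\tau$ is held fixed across
permutations, and a permuted arm whose follow-up ends before $\tau$
has its KM value carried forward. Equal survival implies equal RMST
but not conversely, so these tests can miss crossings whose areas
cancel — that is a property of the estimand, not a bug.

**coxRMST.** The combined test pairs the Wald test of the
one-parameter two-sample Cox model (Breslow ties, Newton iteration,
convergence $|\Delta\beta| < 10^{-8}$, monotone likelihoods flagged
at $|\beta| > 15$) with the permutation RMST test. The naive
Bonferroni combination $2\min(p_{cox}, p_{rmst})$ is conservative
here because the two components are strongly correlated: under the
package's null study conditions its measured size is 0.026 at nominal
0.05. The package therefore calibrates the min-p statistic by the
same permutation stream — the Cox model is refitted and the RMST
difference re-ranked for every label permutation — which restores
exactness (measured size 0.049) while keeping the intended
"PH-directed plus shape-free" pairing. When the observed Cox fit is
non-identified the test falls back to the RMST p-value with a
warning.

**KONP sample-space-partition tests.** At every pooled event time $t$
the sample is partitioned into failed-by-$t$ versus survived-past-$t$
per group, with censored-before-$t$ subjects allocated fractionally
through the group-wise KM estimate ($O_{j,\mathrm{fail}} =
n_j(1 - \hat S_j(t))$, right-continuous). The statistic sums each
2×2 table's Pearson $\chi^2$ (`chi`) or likelihood-ratio
$2\sum O\log(O/E)$ contribution (`llr`, with $0\log 0 = 0$);
degenerate tables (a zero column margin) contribute zero. Calibration
is pure permutation — tables and group KM curves are recomputed for
every relabelling — so the exact form of the imputation affects power,
not validity.

**ABC.** The integrated L1 distance
$\int_0^{\tau_{end}} |\hat S_1 - \hat S_2|$ with
$\tau_{end} = \min$ of the two arms' largest observed times: the KM
curves are never extrapolated beyond their own follow-up. The
integral is an exact rectangle sum on the pooled event-time grid and
the p-value is a permutation tail with $\tau_{end}$ held fixed.
Unlike the other omnibus tests the statistic genuinely lives on the
time scale, so it is not invariant under non-linear time transforms
(the rank-based tests are, bit-for-bit).

**Two-stage procedure.** Stage 1 spends $\varepsilon\alpha$ of the
level on the plain log-rank test ($\varepsilon = 0.5$ by default,
exposed as `split_eps`). If it does not reject, stage 2 applies the
maximally selected crossing weight — $+1$ up to a candidate change
point, $-1$ after, maximized over the pooled event times — and
calibrates that selected statistic by permutation. The overall
p-value $\min(1, p_1/\varepsilon, p_2/(1-\varepsilon))$ keeps the
size at or below $\alpha$ for any split; the standardized (rather
than raw) score is maximized so that change points near the ends of
follow-up are not favoured by scale alone.

## Reconstruction from published curves

`reconstruct_ipd()` rebuilds pseudo individual-patient data from
digitizer output: per-arm curve coordinates plus the number-at-risk
table, optionally the total event count. Within each risk-table
interval the solver alternates between a censoring count (spread
uniformly over the interval — the usual non-informative censoring
assumption, and the main approximation of any such reconstruction)
and integer event counts from the KM ratios, until the at-risk count
at the next risk-table time matches *exactly*.

Two refinements squeeze more out of clean input. First, when the
digitized survival values are noise-free, each drop ratio
$S_k/S_{k-1} = 1 - d_k/n_k$ identifies the integer risk-set size at
the step up to a divisor ambiguity; the solver snaps to the
consistent size nearest the uniform-censoring allocation (and widens
the interval's censoring budget when the ratios demand sizes the
budget forbids). With noisy coordinates no size is numerically
consistent and the solver falls back to plain rounding, so the
refinement never hurts real digitizer output. Second, a terminal drop
to zero satisfies $d = n$ for *any* $n$; because simultaneous deaths
have probability zero under continuous event times, the smallest
consistent risk set is taken — one final death, the remaining
subjects censored before it. When rounding still strands the at-risk
constraint by a subject, the integer event counts are re-balanced
from the latest steps and the adjustment is recorded in the
diagnostics.

Without a total event count, censoring after the last risk-table time
is extrapolated at the rate observed over the earlier intervals (the
uniform-censoring model is global); with one, the final-interval
censorings are iterated to match the reported event total. Subjects
still at risk at the end of the curve are censored there. Digitized
survival values are trusted over implied event counts at sub-subject
magnitude.

`digitize_sample()` produces the idealized digitizer output of an
in-memory dataset (exact KM knots, 7 evenly spaced risk-table rows by
default — the density of a typical published figure), which is how the
round-trip property is tested: at-risk counts reproduce exactly, the
reconstructed KM stays within 0.01 of the input in sup norm, the
hazard ratio within 5%, and every battery p-value within 0.05 of the
original's.

## Simulation harness and study conditions

`scenario_preset()` fixes the package's study conditions, all with
150 subjects per arm:

* `null` — two exponential(1) arms, uniform(0, 5) censoring (about
  20% censored): size checks.
* `ph` — exponential rates 1 vs 1.7: the regime where the log-rank
  is optimal.
* `early` / `late` — piecewise rates (2, 1) / (1, 2) switching at
  t = 0.5 against exponential(1).
* `crossing-1` — exponential(1) vs rates (2, 0.5) switching at 0.5;
  the survival curves cross once at t = 1.5 (solve
  $t = 1 + 0.5(t - 0.5)$), uniform(0, 4) censoring.
* `crossing-2` — rates (2, 0.3, 1.5) with breaks (0.4, 1.5): two
  crossings, near t = 0.97 and t = 2.24.

Event times come from inverse-transform sampling of the cumulative
hazard; `crossing_times()` solves $S_1 = S_2$ exactly for
piecewise-exponential pairs (piecewise-linear cumulative-hazard
difference) and numerically otherwise. `rejection_study()` drives the
Monte-Carlo: each replicate draws its data from a child seed of the
master seed, and each test from a child of the replicate seed keyed
by the method name, so adding a test never perturbs another's stream
and every table is bit-reproducible. A test that errors on a
replicate is recorded as `NA`, never dropped.

The generator emulates the hazard *shapes* that matter for this test
family; it does not emulate covariate-driven heterogeneity,
informative censoring, delayed study entry or interval censoring, so
passing the simulation-based checks says nothing about those
features of real trial data. Left truncation, competing risks and
more than two arms are out of scope throughout the package.

## Problem sizes used by the checks

The packaged checks run at deliberately modest Monte-Carlo scale,
chosen so the whole suite stays comfortably interactive while keeping
the binomial bands meaningful: size control uses 1000 null
replicates with 500 inner iterations for the resampling tests (99%
band [0.032, 0.068] around 0.05), the power orderings use 500
replicates per scenario, exact-enumeration comparisons use the 20
label assignments of a 3-versus-3 sample against 5000 Monte-Carlo
permutations, and the reconstruction round trip covers 50 simulated
scenarios at 200 subjects per arm. The acceptance script re-runs the
same pipeline at 500/300-replicate scale. Production analyses should
keep the 5000-iteration default of `run_battery()`.

## Numerical conventions, degenerate inputs, limitations

* Zero or negative times are rejected at parse time; status must be
  0/1; exactly two group labels are required, the first factor level
  (or first in sort order) is "group 1".
* Subjects are canonically ordered internally, so every statistic
  *and* every seeded permutation p-value is invariant to row order
  of the input.
* `write_ipd()` emits 17 significant digits and `read_ipd()` parses
  through `strtod`, so the file path and the in-memory path give
  bit-identical battery rows.
* Permutation p-values carry the $(1+\cdot)/(1+B)$ correction and are
  floored at $1/(B+1)$ in formatted output; displayed p-values are
  never 0.
* A weighted score with zero variance yields p = 1 when the score is
  also zero and is an internal error otherwise; all-zero covariance
  in the combination tests warns and returns p = 1.
* The KM variance term is omitted where $n_i = d_i$ (curve hits
  zero); RMST variance terms there contribute zero with a warning.
* Known limitations: the MaxCombo `mvn` p-value is asymptotic (use
  the permutation method at small n); RMST tests cannot see
  area-cancelling crossings; reconstruction inherits the uniform
  censoring assumption and cannot be better than the digitization it
  is fed.
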