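---
title: "Methods: probabilistic benefit-risk assessment of methylprednisolone in MS relapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic benefit-risk assessment of methylprednisolone in MS relapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbr)
```

## The decision problem

msbr analyses the treatment decision faced by a representative multiple
sclerosis patient in acute relapse: give high-dose methylprednisolone (at
least 2000 mg cumulatively over at most 31 days), low-dose
methylprednisolone (under 1000 mg over the same window), or no treatment.
The horizon is one relapse, nominally six months; the horizon is a label on
the utilities, not a simulated timeline. Benefit is defined as a "reduced
relapse": improvement of at least one EDSS point within 14–28 days of
treatment start. Harms enter as one pooled non-serious adverse-event branch
plus eleven serious adverse effects, each with up to three outcomes (death,
persistent disability, life-threatening reaction), 26 included
effect–outcome combinations in all.

All effects are arranged in a shared decision tree. Within each benefit
state the serious combinations are treated as mutually exclusive (they are
rare), followed by a non-serious branch and a no-adverse-event branch:
`2 × (26 + 2) = 56` clinical outcomes. For one joint draw of the
probability variables, the outcome probabilities of alternative $A$
factorise as

$$P(\text{benefit}, (j,o)) = e_A^{[\,]}\, q_A(j,o), \qquad
  P(\text{benefit}, \text{NS}) = e_A^{[\,]} \Big(1-\sum q_A\Big) r_A, \qquad
  P(\text{benefit}, \text{none}) = e_A^{[\,]} \Big(1-\sum q_A\Big) (1-r_A),$$

where $e_A^{[\,]}$ is $e_A$ for the reduced-relapse branches and $1-e_A$
for the standard-relapse branches, $q_A(j,o)$ the serious risks and $r_A$
the non-serious risk. Serious risks are shared between the two benefit
branches, and $r_A$ is applied as the probability conditional on no serious
effect; because the serious risks are of order $10^{-3}$–$10^{-2}$, not
rescaling them against $r_A$ changes outcome probabilities only in the
fourth decimal. The expected utility of an alternative in one iteration is
the probability-weighted sum of the outcome utilities. The primary metric
is the **preference rate**: the fraction of Monte-Carlo iterations in which
an alternative attains the highest expected utility, with exact ties (a
measure-zero event, handled only for determinism) split equally.

## Effectiveness and non-serious risk: hierarchical beta-binomial model

Study arms from the packaged tables are combined with a hierarchical
beta-binomial model: arm $i$ has its own improvement probability
$p_i \sim \mathrm{Beta}(\mu M, (1-\mu)M)$ and $x_i \sim
\mathrm{Binomial}(n_i, p_i)$. Integrating $p_i$ out gives a beta-binomial
marginal per arm, evaluated through `lgamma` so the two fractional printed
counts (39.25/94 and 9.2/13, which arise from scale conversions in the
original trial reports) are handled exactly.

The prior is weakly informative: $\mu$ uniform on $(0,1)$ and $1/(1+M)$
uniform on $(0,1)$, i.e. $p(M) \propto (1+M)^{-2}$ — a standard choice for
hierarchical binomial models that keeps the prior sample size proper
without favouring large concentrations. It is stated prominently because
the original analysis's exact non-informative prior is not published with
the main text; the acceptance tolerances on the posterior medians (±0.05)
absorb this prior uncertainty. Sampling is random-walk Metropolis–Hastings
on $(\mathrm{logit}\,\mu, \log M)$ with independent Gaussian steps
(defaults 0.6 and 1.4, giving 20–50 % acceptance on all five packaged
fits), 55,000 iterations with 5,000 burn-in and no thinning. The posterior
median of $\mu$ from a 2-D quadrature over $(\mu, 1/(1+M))$ agrees with
the sampler to within ±0.01 on small instances (tested).

The evaluation consumes the draws of the **population mean** $\mu$, not
study-level predictive draws: the assessment targets a representative
patient of the population, and the wide posteriors already carry the
between-study heterogeneity relevant at that level. A predictive estimand
would widen all three alternatives' distributions jointly without changing
their ordering.

The no-treatment alternative uses the placebo fits for both effectiveness
and non-serious risk. The low-dose non-serious risk cannot be estimated
from data (two trials, ten patients each, zero events); each value is
instead drawn uniformly between the paired placebo and high-dose posterior
draws of the same iteration.

## Serious risks: reporting-ratio upper limits and interval distributions

Serious adverse effects are too rare for the trials (two events across
>300 high-dose patients), so the package consumes upper limits on the true
population risks computed as reporting ratios in spontaneous case-report
collections: the fraction of a dose group's reports that carry the
effect–outcome after hierarchical outcome classification (death >
persistent disability > life-threatening, per effect within a report) and
that qualify for the numerator — drug suspected or interacting, or
concomitant with no other drug implicated, and time to onset at most 180
days (waived for osteonecrosis, which is hard to date). A report with a
missing onset cannot demonstrate onset within 180 days and is excluded
from the numerator (switchable via the exemption flag). The 26 printed
limits ship as a fixture; the computation itself is exercised on synthetic
collections with known truth, since the underlying report database is not
redistributable. Where the printed high-dose limit is 0.00 — clearly not
an upper bound — the low-dose limit is substituted, following the source
table's own footnote.

A limit says nothing about the distribution below it, so the evaluation
assigns one of four families over $[0, L]$: uniform (the most pessimistic)
or a truncated exponential with rate $k/L$ for $k \in \{5, 50, 500\}$,
whose means are $0.19L$, $0.020L$ and $0.0020L$. Draws use the inverse
CDF. Within an iteration the low- and high-dose values of a combination
are sampled independently (the source is silent on cross-dose
correlation), and the no-treatment value is $\pi (q_{\text{low}} +
q_{\text{high}})/2$ with background proportion $\pi \in [0, 0.5]$ — this
derivation couples the no-treatment risks to the active ones within the
iteration, which is what makes iteration-level comparison meaningful.
Sampling is also independent across the 26 combinations; the tree treats
the effects as mutually exclusive branches, and nothing in the source
suggests sampling correlation.

## Utilities: uniform sampling on an order-constrained polytope

The 56 outcomes are grouped into 16 utility classes: 2 benefit states × 8
adverse-effect classes (none, non-serious, life-threatening, mild /
intermediate / severe persistent, quick lethal, painful lethal). Among
persistent outcomes, osteonecrosis and diabetes are mild (manageable, no
life-threatening trigger); cardio-pulmonary distress, ventricular
arrhythmia/cardiac arrest and seizure are severe; psychosis, myopathy,
hepatotoxicity and gastrointestinal haemorrhage are intermediate. Lethal
pancreatitis, cardio-pulmonary distress and gastrointestinal haemorrhage
are painful deaths; lethal anaphylaxis and cardiac arrest are quick. The
source text does not assign lethal diabetes, hepatotoxicity or seizure;
they are placed in the painful class on account of their protracted
clinical course, and the mapping is exposed as configuration
(`class_map`). The placement of the life-threatening class above the mild
persistent class follows the column ordering of the published utility
figure; it too can be overridden by building a custom system.

Each class utility starts as an independent standard uniform variable and
is conditioned on the qualitative relations; the resulting joint law is
exactly the uniform distribution on the constraint polytope. The
constraints are: the within-benefit chain from no adverse event down to
painful death; reduced beats standard at every adverse-effect class; a
reduced relapse with a non-serious event beats a standard relapse with
none; a block constraint $\min(\text{non-lethal}) \ge \max(\text{lethal})
+ \delta$ with $\delta \in [0, 0.99]$ (risk aversiveness); two extra
relations for relapses starting at EDSS 4 and one for EDSS 5, encoding
that a one-point improvement does not outweigh a life-threatening event or
a serious persistent disability. The block constraint spans all twelve
non-lethal and all four lethal classes — the published figure's zigzag
line separates the two blocks, not individual pairs.

Sampling is coordinate-wise Gibbs (compiled, using R's RNG so `set.seed()`
governs chains): each class utility is resampled uniformly on the interval
its neighbours and the $\delta$ gap allow; the conditional of a uniform
joint is uniform, so sweeps leave the target invariant. Defaults: burn-in
1,000 sweeps, thinning 5, one fresh chain per scenario seed, initialised
at a topologically ordered, evenly spaced feasible point with the lethal
block compressed below the gap. Gibbs marginals match plain rejection
sampling on small systems (KS < 0.02 at n = 20,000, tested) and analytic
triangle means on two-class systems. The opaque $\delta$ is interpretable
through a standard gamble: `gamble_indifference()` reports the lethal-risk
probability at which the typical patient is indifferent between the status
quo and gambling between the best and worst outcomes (about 6 % at
$\delta = 0.5$, about 1 % at $\delta = 0.9$ under the EDSS-4 system).

## Evaluation, sensitivity grid and uncertainty attribution

A scenario is defined by the risk family, $\pi$, $\delta$, the EDSS level
and the iteration count (default 10,000). Per iteration, effectiveness and
non-serious draws are paired across alternatives by iteration index from
their independent posterior streams; serious risks and one utility row are
drawn fresh; expected utilities and preference rates follow. Every source
of randomness derives a named substream from the scenario's master seed
(`derive_seed()`), so any stage reproduces bit-identically in isolation.

The default sensitivity grid crosses 4 risk families × $\pi \in \{0, 0.10,
0.25, 0.50\}$ × $\delta \in \{0, 0.1, \ldots, 0.9, 0.99\}$ × EDSS
$\{4, 5\}$ — 352 cells. The source states the ranges of $\pi$ and
$\delta$ but not the grid levels; these levels anchor the published
reference scenario ($k = 5$, $\pi = 0.10$, $\delta = 0.4$, EDSS 4) as an
interior cell. The grid runs at 2,000 iterations per cell by default,
which resolves preference rates to about ±1 point and keeps a full grid
under a minute; per-cell seeds derive from the base seed and the cell
label. One consequence of grid-level reconstruction is worth noting: the
share of cells in which low-dose methylprednisolone is argmax-preferred
comes out at 5.1 % here (all such cells at $\pi = 0.5$), straddling the
published "less than 5 % of scenarios" — a bound that is inherently
grid-dependent.

`fix_variables()` performs median-fixation uncertainty attribution:
selected draw streams (all probability variables, all utility variables,
or named groups) are replaced by their per-variable medians and the
scenario re-evaluated with everything else unchanged. Fixing the
probability variables concentrates preference rates far more than fixing
the utilities, reproducing the published conclusion that posterior
uncertainty in effectiveness and risks — not utility uncertainty — is what
caps the high-dose preference rate.

## What the synthetic-data module emulates

`simulate_study_arms()` generates arms from the exact generative model the
fitter assumes, for parameter-recovery and coverage checks.
`simulate_case_reports()` generates the regime in which the
reporting-ratio bound is conservative: every true case reported, drug
suspected, onset within 180 days, plus non-case padding reports that
dilute only the denominator (concomitant role with another drug
implicated). Passing these checks shows the machinery is correct under its
assumptions; it does not validate the assumptions themselves against real
pharmacovigilance data, where under-reporting of cases and numerator
contamination both occur, nor does it emulate coding or term-mapping
noise.

## Numerical choices and degenerate inputs

* Probability conservation over the 56 outcomes holds to 1e-12 and is
  enforced by construction, not renormalisation.
* A risk limit of zero yields a degenerate all-zero risk stream rather
  than an error; a printed zero high-dose limit is substituted by the
  low-dose limit before evaluation (fixture flag).
* `trunc_exp_mean()` uses `expm1` so the $k \to 0$ limit recovers the
  uniform mean $L/2$ without cancellation.
* Outcome ordering in the tree is deterministic (effects alphabetical,
  outcomes by severity), and preference-rate ties split equally, so equal
  seeds give bit-identical results.
* Requesting more iterations than available posterior draws is an error
  unless resampling with replacement is explicitly enabled.
* Infeasible constraint systems (a cycle, or $\delta > 0.99$) are rejected
  at construction with a diagnostic naming the offending classes.

## Problem sizes used in the packaged checks

The packaged tests fit the five posteriors at the default 55,000-iteration
chains, run the reference scenario at 10,000 iterations and the full grid
at 2,000 iterations per cell; oracle comparisons (quadrature, rejection
sampling, closed forms) run at reduced sizes chosen so each agreement band
is several Monte-Carlo standard errors wide.

## Known limitations

* The prior and sampler tuning of the original analysis are not published;
  posterior medians here match the published ones to well within ±0.01,
  but tail quantiles may differ more.
* The qualitative edge set beyond the explicitly described relations is
  reconstructed from the published group-ordering narrative; alternative
  readings would change utilities, and the constructor accepts custom
  systems for exactly that reason.
* Risk limits are consumed as printed at two decimals in percent; the
  underlying unrounded reporting ratios are not recoverable, which is why
  the printed "Total" rows are not used as exact checks.
* No meta-regression on route, dose or assessment day; no study-quality
  weighting; no QALY-style time aggregation (deliberately avoided by the
  utility method).
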