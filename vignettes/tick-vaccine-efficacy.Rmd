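---
title: "Stage-structured efficacy analysis of anti-tick cattle vaccine trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-structured efficacy analysis of anti-tick cattle vaccine trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickvax)
library(dplyr)
```

## The problem

Anti-tick vaccines based on concealed or conserved antigens (BM86,
subolesin/akirin) do not kill ticks outright the way an acaricide does.
Their effect is distributed across the parasite's life cycle: vaccinated
hosts feed fewer larvae to repletion, a smaller fraction of engorged larvae
molt to nymphs, engorged females lay lighter egg masses, and those eggs
convert less mass into larvae. A trial therefore observes, per animal and
tick species, a chain of stage outcomes rather than a single endpoint, and
the analysis must compress that chain into one interpretable efficacy
number.

`tickvax` implements that analysis for the standard two-breed (Bos indicus
and B. indicus x B. taurus crossbred), five-arm (three single subolesin
antigens, their combination, adjuvant-only control), three-tick-species
design: the three-host species *R. appendiculatus* and *A. variegatum*,
whose larvae, nymphs and adults each feed separately on the host, and the
one-host *R. decoloratus*, which completes all stages on one animal so that
only the adult-derived outcomes are observable.

## Stage reductions and the cumulative efficacy index

Seven stage parameters are tracked. For counts of successfully engorged
ticks (DL larvae, DN nymphs, DA adult females), molting proportions (DMn
larva-to-nymph, DMa nymph-to-adult), egg mass per engorged female (DO,
oviposition) and larval mass per gram of eggs (DF, fertility), the percent
reduction is the same survival-ratio formula in the group-level measured
quantity $x$:

$$D = 100\,\bigl(1 - x_\text{vaccinated} / x_\text{control}\bigr).$$

A reduction can be negative (the vaccinated arm outperforming control) and
is capped above by 100. The cumulative vaccine efficacy over the life cycle
multiplies *survival fractions*:

$$E = 100\,\Bigl(1 - \prod_{i \in \text{included}} \bigl(1 - D_i/100\bigr)\Bigr).$$

A literal product of the $D_i$ themselves would be dimensionally
inconsistent (percentages multiplied together); the survival-fraction
product is the reading that regenerates the published group efficacies from
their per-stage reductions, and it has the right algebra: it is monotone in
each included reduction, maps reductions in $[0,100]$ to an efficacy in
$[0,100]$, and composes -- $1 - E_{ab}/100 = (1-E_a/100)(1-E_b/100)$ for
disjoint parameter sets. These properties are asserted in the test suite.

**Gating.** Only parameters whose vaccinated-vs-control difference is
statistically significant enter the product; excluded parameters contribute
a factor of one. Significance uses the strict inequality $p < \alpha$ with
$\alpha = 0.05$ and no multiple-testing adjustment, mirroring the
per-parameter convention of the trials this design follows. A significant
*negative* reduction is reported but never auto-included: including a harm
would push $E$ below zero, and whether that is meaningful is a judgement we
leave behind the explicit `include_negative` flag.

**Rounding.** $E$ is computed on unrounded reductions by default.
`printed_integers = TRUE` recomputes from integer-rounded percentages,
matching published tables that print integers; display rounding is
half-away-from-zero (`round_half_up()`), so 46.5 prints as 47.

```{r}
ref <- reference_reductions()
eff <- vaccine_efficacy(ref, printed_integers = TRUE)
head(eff, 3)
```

## The significance gate

The per-parameter test compares the two arms of four animals each. The
default `chi_square_pooled` method pools the animals of an arm into one
2x2 arm-by-outcome table -- engorged vs not engorged out of applied ticks,
molted vs not molted out of engorged -- and applies Pearson's chi-square
without continuity correction. How a contingency test was originally
constructed for four biological replicates per arm is not fully specified
by the field's convention; pooling is the construction that yields a
well-defined 2x2 table at this design size, and it is flagged as an
interpretation in the documentation.

The continuous mass parameters (DO, DF) have no natural counts. Under the
pooled method they are scaled to integer pseudo-counts at
`mass_unit_scale` units per gram (default 1000, i.e. milligram
resolution): oviposition treats each engorged female as a budget of one
gram of potential egg mass (valid while per-female egg mass stays below
1 g, comfortably true for these species), fertility treats larval mass as
"successes" out of egg-mass units. A chi-square on masses is statistically
dubious however you scale it, so a `rank_per_animal` alternative -- an
exact Mann-Whitney test across the 4 + 4 per-animal values -- is provided
and selectable for any parameter class. Expected cells below one set a
`small_sample` flag on the result rather than silently proceeding; a table
with a zero outcome margin is reported test-undefined and not significant,
while an arm with no trials at all is an error.

Supporting comparisons use the field's standard tools: Welch's
unequal-variance t test for the breed contrast of total efficacy (n = 2
species in B. indicus vs 3 in crossbred), classic one-way ANOVA for
per-timepoint antibody comparisons, and tie-corrected Spearman correlation
(mid-rank Pearson with the t approximation for the p-value; exact +/-1
correlations report p = 0 as the limit of that approximation).

## Antibody correlates and the reduction threshold

Antibody titers are the OD450 readings themselves, at the fixed optimal
1:1000 serum dilution -- no endpoint-titer transformation. The
time-course analysis tests vaccinated against control per (breed, coated
antigen, bleed day) and codes significance at p < 0.05 and p < 0.005.

The correlate-of-protection analysis pools all twenty individual animals of
a (breed, tick species) panel -- four animals in each of the five arms,
control included -- and correlates each animal's day-60 titer against its
*raw* stage values (counts, molting proportions, masses), not group-level
reductions: individual animals are the unit of analysis at n = 20.
Parameters enter only if they were significantly affected under at least
three of the four vaccine formulations (`eligible_parameters()`), the
published selection rule. A protective association is a significant
*negative* rho ($p \le \alpha$, inclusive here, following the source
convention for this analysis).

`reduction_threshold()` then asks: how large must the mean stage reduction
be before a significant negative correlation appears? It returns the
smallest mean reduction among significant outcomes, flagged `separating`
when no non-significant outcome sits at or above it. Per-parameter mean
reductions average the included group reductions across formulations
(non-included entries count as zero reduction); units differ across
parameters, so cross-parameter averaging is left to this summary layer and
recorded per parameter.

## The synthetic trial generator

No per-animal data from the reference trials is distributable, so the
generator is a first-class module: every downstream stage is exercised on
data whose ground truth is known.

Stage counts follow beta-binomial chains. Each animal's engorged larvae are
drawn from `BetaBin(300, p_L (1 - e_DL))`, molts from a beta-binomial on
the engorged count, and so on down the chain; the applied numbers are fixed
per stage (300 larvae, 200 nymphs per ear -- 400 per animal for analysis,
with a config switch -- and 30 adults at one male per three females, so 22
applied females) because that is how the challenge protocol works: each
stage is applied from laboratory stock, not fed forward from the previous
stage's survivors. The beta-binomial (rather than plain binomial) reflects
that four animals per arm sharing husbandry plausibly overdisperse;
`dispersion` is the intraclass correlation, default 0.05, configurable to
zero. Masses are log-normal (guaranteeing positivity) parameterised by
arithmetic mean and CV (default 0.2). One-host records draw engorged
females directly from the applied larvae with a whole-chain yield (default
0.15), and carry no larval or nymphal fields. B. indicus animals receive no
one-host challenge, as in the reference design.

Baseline control-arm rates (larval engorgement 0.5, molting 0.8, nymphal
engorgement 0.5, nymphal molting 0.8, female engorgement 0.7, egg mass
0.25 g per female, 0.5 g larvae per gram of eggs) were chosen once as
realistic for fed *Rhipicephalus*/*Amblyomma* challenges of this size. The
default per-stage effect sizes are not free knobs: they are taken directly
from the reference reduction table (starred reduction / 100, zero
otherwise), so the default simulated trial reproduces the study's own
observed conditions in expectation.

The antibody model gives vaccinated animals a piecewise-linear mean OD
trajectory over the bleed schedule (rise after each dose; day 45 sits 70%
into the second response; a documented `third_dose_decline` mode turns the
third increment into a decline), per-animal frailty, per-reading Gaussian
noise, truncation at zero, and cross-reactivity 0.85 against heterologous
coated antigens (the antigens are about 75% identical at the protein
level, and the combined formulation is homologous to all). The
titer-to-protection link (`link_strength`) is off by default so
correlation analyses can be exercised under both the null and the
alternative; when on, a shared per-animal frailty scales both the titer
shift and the realised effect.

Dose metadata (days 0/30/60, 100 ug, 2 mL) is recorded for the manifest
but never read during generation -- changing it provably leaves the data
byte-identical, which the suite asserts.

## Numerical and design choices

- Group-level molting and mass ratios pool across animals (total molted /
  total engorged; total egg mass / total females; egg-mass-weighted larval
  yield), matching the pooled gate construction. A zero pooled denominator
  makes the value undefined and, in a control arm, raises a
  degenerate-control error rather than a silent `NaN`.
- Zero entries in a reduction table can mean "no reduction observed" or
  "suppressed as non-significant"; the reference table stores both the
  value and the star so either convention is recoverable.
- Replication: every simulation is a pure function of `(config, seed)`;
  the pipeline records a config hash, seed and input-file digests in its
  manifest, and replaying a manifest reproduces every table exactly.
- Problem sizes used by the test suite: the type-I calibration of the
  pooled gate runs 2,000 single-species null trials at dispersion zero
  (the pooled 2x2 test is only nominally calibrated without between-animal
  overdispersion -- with it, pooling is anticonservative, one more reason
  the rank gate exists); effect recovery runs 500 replicate trials at each
  of effects 0.2/0.5/0.8 and requires mean bias under 3 percentage points;
  rank-correlation code is checked against a brute-force mid-rank oracle
  on all input lengths up to six, ties included.

## What the synthetic data does and does not show

Passing tests on generated trials demonstrate that the estimators recover
known effects, that the gate holds its nominal size under the null, and
that the pipeline's plumbing is lossless and reproducible. They do not
validate the biological model: real stage outcomes correlate across stages
within an animal (the generator's chain draws are conditionally
independent given the frailty), real antibody kinetics are not piecewise
linear, and real overdispersion need not be beta-binomial. Conclusions
about a real trial rest on the real data fed through
`read_stage_records()`/`read_serology()`, with the generator serving as
scaffolding for verification.

## Known limitations

- The pooled chi-square on scaled masses inherits an arbitrary unit scale;
  results at different `mass_unit_scale` values differ. The rank gate is
  the defensible alternative and both choices are logged in the manifest.
- With four animals per arm the exact Mann-Whitney test cannot reach
  p < 0.05 two-sided unless separation is complete (minimum two-sided p is
  2/70); the rank gate is therefore conservative at this design size.
- The breed comparison has n = 2 vs 3 efficacy values per formulation;
  Welch's test at these sizes is fragile and its p-values should be read
  qualitatively.
- One published group efficacy is not reproducible from its own printed
  starred reductions under any rounding of the survival-fraction product;
  the regression suite documents the discrepancy rather than adjusting
  the table.
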