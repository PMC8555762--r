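---
title: "Scoring defensive functioning from a forced-distribution Q-sort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring defensive functioning from a forced-distribution Q-sort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrsq)
```

## The instrument

The DMRS-Q assesses an individual's defensive functioning from an
observer's Q-sort of 150 descriptive statements. Each statement (item)
expresses one concrete manifestation of one of 30 defense mechanisms;
every defense owns exactly 5 items. The 30 defenses are organized in the
standard hierarchy of defensive adaptiveness:

* seven **defense levels**, from L1 (action defenses: acting out,
  help-rejecting complaining, passive aggression) up to L7 (high-adaptive
  defenses: affiliation, altruism, anticipation, humor, self-assertion,
  self-observation, sublimation, suppression), with the neurotic level L5
  split into L5a (hysterical: dissociation, repression) and L5b (other
  neurotic: displacement, reaction formation);
* three **defensive categories**: C1 immature (levels 1–4), C2 neurotic
  (levels 5–6), C3 mature (level 7); C1 subdivides into C1a depressive and
  C1b other-immature defenses.

`load_item_bank()` returns this structure from a denormalized, auditable
CSV shipped with the package (one row per item with explicit defense,
level and category codes) and re-checks every structural invariant on
every load: 150 unique items, 30 defenses with 5 items each, hierarchy
codes consistent with `defense_hierarchy()`. The hierarchy is never
inferred from item ordering, so a corrupted bank file fails loudly rather
than scoring silently wrong.

One item (79, an altruism statement) carries a clearly flagged placeholder
text because its official statement is not available in the public item
listing; its membership and scoring are unaffected, only its display text
is synthetic.

## The forced distribution

A completed rating assigns every item to one of seven ordinal ranks with
fixed pile sizes:

| rank | meaning | items |
|---|---|---|
| 1 | not used at all | 60 |
| 2 | very rarely used | 30 |
| 3 | slightly/rarely used | 20 |
| 4 | sometimes used | 16 |
| 5 | often used | 10 |
| 6 | very frequently used | 8 |
| 7 | almost always used | 6 |

The distribution forces ipsative scores: every rater spends exactly the
same rank budget, so scores express the *relative* salience of defenses
within one individual, not absolute frequencies. `validate_sort()` is
total — violations (missing or duplicated items, per-rank count deltas)
come back as data, and scoring refuses any sort that is not exactly valid,
attaching the validation report to the error condition. Custom
distributions are accepted as research configuration, but scoring warns on
them: only the default has published semantics.

Two constants follow from the capacities and are asserted rather than
assumed. The total rank mass of any valid sort is
$\sum_r c_r \cdot r = 60 + 60 + 60 + 64 + 50 + 48 + 42 = 384$, and the
scoring normalizer is $384 - 150 = 234$ (`score_normalizer()` recomputes
it for any distribution).

## Quantitative scoring

For defense $d$ with item set $I_d$ (five items), the individual defense
score is

$$\mathrm{score}_d = \frac{\left(\sum_{i \in I_d} \mathrm{rank}_i\right) - 5}{234} \times 100 .$$

Subtracting 5 re-zeroes a defense whose items are all "not used at all";
division by 234 makes the 30 scores a partition of 100:
$\sum_d \left(\sum_{i \in I_d} \mathrm{rank}_i - 5\right) = 384 - 150 = 234$
identically over valid sorts. Level scores sum the member defenses, the
categories sum the member levels, and the Overall Defensive Functioning
index is the level-weighted mean on the 1–7 adaptiveness scale:

$$\mathrm{ODF} = \sum_{l=1}^{7} \frac{L_l}{100} \, l .$$

All aggregation happens at full floating precision; reports round to two
decimals only at rendering time.

### Attainable ODF range

Although the scale runs 1–7, the forced distribution cannot concentrate
all mass on one level. Writing $\ell_i$ for the level of item $i$'s
defense, ODF has the item-level form
$\mathrm{ODF} = (\sum_i \ell_i \,\mathrm{rank}_i - 675) / 234$ with
$675 = 5 \sum_d \ell_d$, so extremizing ODF is the assignment problem of
pairing the fixed multiset of ranks with the fixed multiset of item
levels. By the rearrangement inequality the optimum pairs them
comonotonically, which is exactly what `extremal_odf_sort()` constructs
(items ordered by level, piles filled from rank 7 down, ties broken by
ascending item id):

```{r}
bank <- load_item_bank()
full_profile(extremal_odf_sort(bank, maximize = TRUE), bank)$odf   # 1513/234
full_profile(extremal_odf_sort(bank, maximize = FALSE), bank)$odf  #  553/234
```

The test suite confirms the bounds by the independent item-level identity
on every sort it generates and checks that seeded random search never
escapes them. A single advisory flag `odf_below_4` is attached to
profiles — values below 4 are the range reported for severe depression and
personality pathology — and no further clinical banding is invented.

## The Defensive Profile Narrative

The qualitative output comprises the 14 items placed in the two highest
ranks (6 items at rank 7, 8 at rank 6), each labeled with its defense and
level. The source listing of the instrument does not fix an ordering for
these statements, so the package imposes one for determinism: rank 7
("almost always used") before rank 6, ascending item id within rank.
Statements are concatenated as printed, without pronoun harmonization.
`render_report()` serializes the combined report as lossless JSON
(round-trips through `parse_report()`), markdown, or a flat 45-row score
table (30 defenses + 9 levels + 5 categories + ODF) ready for plotting;
chart rendering itself is left to downstream tools.

## The synthetic-rater model

No clinical sorts are published, so the simulator generates them. A
subject is a latent profile $w$: 30 nonnegative weights summing to 1, the
target share of defensive mass per defense. A rater perturbs item
attractiveness with Gaussian noise:

$$a_i = w_{d(i)} + \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$

then items are sorted by $a_i$ (ties broken by ascending item id) and
filled into the piles from rank 7 down, so *every* generated sort is valid
by construction. Design choices, made once:

* **Gaussian noise** on the attractiveness scale — the simplest
  exchangeable perturbation; nothing in the instrument's description
  constrains the rater error process.
* **Deterministic tie-break** by item id, so `noise_sd = 0` is exactly
  reproducible and recovers the weight ordering of defense scores up to
  capacity-induced ties.
* **Explicit seeds everywhere**; generators save and restore the caller's
  RNG state, and panel cells derive per-(subject, rater) seeds from the
  rater seed and subject index so a panel is reproducible as a whole.
* **Subject heterogeneity** in simulation studies comes from a symmetric
  Dirichlet(1) over the 30 weights (`random_profile()`): uniform on the
  simplex, giving typical weights of order $1/30 \approx 0.033$ with
  realistic spread between prominent and absent defenses.

What the simulator emulates is the *measurement process*: raters of
varying fidelity producing forced sorts around a stable per-subject
profile. What it does not emulate: correlated rater biases (halo effects,
systematic leniency), item-level difficulty differences within a defense,
or session-to-session change in the subject — so simulation results
exercise the scoring and agreement machinery, they do not validate the
instrument against real clinical behavior.

## Inter-rater agreement

`icc()` implements the two-way random-effects, absolute-agreement
intraclass correlations from the mean squares of the subjects × raters
score matrix ($n$ subjects, $k$ raters):

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},
\qquad
\mathrm{ICC}(2,k) = \frac{MS_R - MS_E}{MS_R + \frac{MS_C - MS_E}{n}} .$$

The two-way random form treats raters as a random sample of trained
coders, which matches how the instrument is used; the form is always
reported alongside the estimate. Numerical conventions: a matrix with
zero total variance is a *defined* degenerate case (estimate 1, flagged)
rather than 0/0; negative estimates are reported as computed, flagged,
never truncated at zero; variance components are exposed so confidence
intervals can be added downstream. `q_correlation()` gives the standard
Q-methodology agreement between two complete sorts — Spearman or Pearson
correlation across the 150 paired ranks.

`reliability_experiment()` reproduces the reliability *study design*
(panel of raters, ICC per scale) on synthetic data. With zero rater noise
every scale's ICC is exactly 1; as noise grows the ICC decays to zero.
The regression suite verifies the decay on a five-point noise grid
{0.003, 0.01, 0.03, 0.06, 0.12} with 20 replicates per point: the grid
spans the decay transition for Dirichlet(1) subjects (weights of order
0.033), because beyond full decorrelation the ICC of a finite panel
fluctuates around zero and adjacent noise levels are no longer ordered —
the near-zero tail is asserted separately at noise 1. Published ICC
values from clinical samples are *not* reproduction targets: the
underlying ratings are not available, so the package reproduces the
statistics and the design, not the numbers.

## Problem sizes and numerical tolerances

The shipped test suites use: 1,000 seeded random sorts for the
conservation identities (each of defense, level and category mass summing
to 100 within $10^{-9}$), 10,000 for the ODF bound/identity sweep, panels
of 8 subjects × 3 raters for the reliability grid, and brute-force ANOVA
oracles on 5 × 3 matrices checked to $10^{-9}$. These sizes give
Monte-Carlo standard errors comfortably below every asserted margin while
keeping a full run around a minute on one core.

## Known limitations

* Ipsative scores are relative by design: two subjects with identical
  profiles but different absolute defensive activity are
  indistinguishable.
* The engine scores completed sorts; it does not model the rater's
  decision process, and the simulator's noise parameter is a free
  abstraction, not calibrated to trained vs untrained human raters.
* No population norms are packaged, so profiles carry no normative
  comparison — only the `odf_below_4` advisory flag.
* Item 79's display text is a placeholder (flagged in the bank); all
  scoring is unaffected.
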