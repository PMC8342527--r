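---
title: "Methods: correlation networks and change-score analysis of checkup cohorts"
author: "checkupnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation networks and change-score analysis of checkup cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkupnet)
```

## The analysis problem

Periodic health checkups produce subject-by-variable tables that mix
continuous clinical measurements (spirometry, muscle mass, grip strength,
CRP, BMI) with ordinal lifestyle questionnaire answers (drinking volume and
frequency bands, smoking status, exercise). Because many of these variables
are mutually entangled — smoking with drinking, both with lung function —
naive pairwise correlation screens surface large numbers of confounded
associations. `checkupnet` implements an unbiased screening pipeline for
such data:

1. **Quantification** — ordinal questionnaire answers become numbers; in
   particular, weekly ethanol grams are reconstructed as the product of the
   volume-band mean (g/day) and the frequency-band mean (days/week).
2. **Screening** — every variable pair gets a pairwise-complete Pearson
   correlation; categorical-continuous pairs additionally get the
   correlation ratio $\eta$ as an ANOVA-scale effect size.
3. **Independence filtering (PCIT)** — first-order partial correlations over
   every variable trio eliminate associations explainable by any single
   third variable.
4. **Network reporting** — surviving edges are ranked by $|r|$, editorially
   known associations are removed, the top $k$ are kept and exported as a
   DOT diagram.
5. **Longitudinal confirmation** — with two checkups per subject, per-subject
   change scores are correlated and tested with a compound significance
   rule.

A seeded synthetic cohort generator with recorded ground truth makes every
step testable end to end.

## The PCIT elimination rule

For a trio of variables $x, y, z$ with direct correlations
$r_{xy}, r_{xz}, r_{yz}$, the three first-order partial correlations are

$$ r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}} $$

and analogously for the rotations. The trio's tolerance is the mean ratio of
partial to direct correlation,

$$ \varepsilon = \tfrac{1}{3}\left( \frac{r_{xy\cdot z}}{r_{xy}} +
   \frac{r_{xz\cdot y}}{r_{xz}} + \frac{r_{yz\cdot x}}{r_{yz}} \right), $$

and the connection $x$–$y$ is *discarded* if
$|r_{xy}| \le |\varepsilon\, r_{xz}|$ **and**
$|r_{xy}| \le |\varepsilon\, r_{yz}|$. An edge is significant only if no
third variable among the remaining $p - 2$ discards it; a single discarding
$z$ suffices to remove it. This is a *relative* tolerance, not a partial
correlation threshold: the symmetric confounding trio
$(r_{xz} = r_{yz} = 0.5,\ r_{xy} = 0.25)$ is discarded
($\varepsilon r_{xz} \approx 0.298 \ge 0.25$), while the proportionally
identical strong trio $(0.9, 0.9, 0.81)$ is kept
($\varepsilon r_{xz} \approx 0.446 < 0.81$).

```{r pcit-anchors}
partial_correlation(0.6, 0.5, 0.4)   # 0.5040
trio_tolerance(0.5, 0.5, 0.5)        # 2/3; symmetric trios give 1/(1+r)
```

**Assumptions and limits.** PCIT sees only the correlation matrix: it
removes the effect of one confounder at a time and cannot account for joint
effects of several, nor for unmeasured latent variables, nor does it orient
edges. Ordinal variables enter through their numeric encodings, so the
"correlations" for those pairs are Pearson coefficients of scored levels.

**Numerical choices.** The printed formulas divide by $r$ and by
$\sqrt{1 - r^2}$ without guards. We clamp direct-correlation magnitudes
below $10^{-12}$ to $10^{-12}$ (sign preserved) in the ratio terms, and
floor $1 - r^2$ at $10^{-12}$, keeping $\varepsilon$ finite; because the
discard comparison is against $|\varepsilon r|$, a true-zero flanking
correlation still cannot discard a nonzero edge. The discard comparison uses
`<=` at double precision with no tolerance — boundary ties are measure-zero
on real data. Two independent implementations (a vectorised scan and a
literal scalar triple loop) are kept and must agree exactly; the test suite
checks this on hundreds of random matrices. Complexity is $O(p^3)$ with no
pruning, which is ample for the tens-to-hundreds of checkup variables this
package targets. Variables whose matrix entries are unavailable (too few
pairwise-complete observations, or zero variance) are removed before the
scan, most-missing first; per-entry sample sizes are reported in the
`correlation_matrix` object because pairwise-complete estimation can mix
denominators across entries.

## Questionnaire quantification

Weekly grams are `volume_mean * frequency_mean`. Band means default to
midpoints of closed bands; an open-ended top band gets its lower bound plus
half the preceding band's width (for example ">60 g/day" scores 70.5). The
four drinking categories split weekly grams at 100 and 350 g/week with
lower-open/upper-closed intervals, so "more than 350 g per week" is heavy
and exactly 350 is moderate; never is exactly zero. The 350 g/week heavy
threshold is the conventional heavy-drinker definition in Japanese checkup
cohorts; 100 g/week for light/moderate matches the descriptive
change-binning threshold used in the longitudinal analysis. Both cutoffs and
all band means are configuration, not constants, because answer-band
definitions vary between questionnaires.

## Longitudinal change-score testing

For paired subjects, `delta = followup - baseline`. The association between
an exposure change and an outcome change is summarised by the Pearson
correlation $R$ of the deltas, $t = |R|\sqrt{n-2}/\sqrt{1-R^2}$ with
$\mathrm{df} = n - 2$, and the two-tailed tail probability of $t$. The
declared rule is *compound*: significant only when $p < 0.05$ **and**
$|R| > 0.05$. At cohort scale ($n$ in the thousands) the $p$-threshold alone
is nearly vacuous — $R = 0.04$ at $n = 10{,}000$ has $p \approx 6\times
10^{-5}$ — so the magnitude floor is what keeps trivial effect sizes out.
Both thresholds are overridable parameters. Trend lines are ordinary least
squares of the outcome delta on the exposure delta. Strata (sex, stable
drinking category, and arbitrary predicates) re-run the identical machinery
on the surviving subjects.

## What the synthetic generator emulates

The generator's defaults encode the cohort structure the pipeline is
designed for: $n = 6036$ cross-sectional subjects (1765 longitudinal), age
60.0 (SD 13.0) years, 61.2% male, drinking mix 26.4/28.5/36.0/8.7% across
never/light/moderate/heavy, FVC 3.60 (0.90) L falling by 0.10 L over five
years (FEV1 2.71 (0.72) L, −0.16 L), smoking mix 49.5/39.1/10.6%. Planted
structure: a direct alcohol–FVC association of $r = 0.35$, alcohol–muscle
0.39, alcohol–grip 0.30, FVC–FEV1 0.85, muscle–grip 0.60, and a smoking
confounder loading $+0.20$ on alcohol and $-0.25$ on FEV1 (inducing an
indirect alcohol–FEV1 correlation of the product with no direct edge).
Alcohol change over the interval is exactly zero for 53.3% of subjects,
under 100 g/week in magnitude for 34.8% and at least 100 g/week for 11.9%;
the FVC change mean is shifted by `attenuation_beta` litres per +100 g/week
of alcohol change (default 0.025, yielding a population delta-correlation
near 0.065 at the default noise level;
`attenuation_for_delta_correlation()` solves for the beta that hits any
requested delta-correlation, accounting for the flooring of decreases at
zero grams).

**Construction.** All planted structure lives in one joint Gaussian latent
space, whose correlation matrix is verified positive definite before
sampling; infeasible requests fail fast. Marginals are then transformed:
linear for continuous variables, lognormal for CRP, threshold for sex, and
a monotone step map for drinking — each latent quantile lands on one
(volume, frequency) answer combination whose product of band means is the
grams value, so `quantify_weekly_alcohol()` reproduces the generator's
grams column bit-exactly and grams are uniform over the achievable levels
within each category band. Discretised marginals attenuate observed-scale
correlations relative to latent ones; each planted target is therefore
divided by the exact attenuation factors
$\lambda = \mathrm{cor}(g(Z), Z)$ of its two marginals (computed in closed
form for step maps, by quadrature for smooth ones), so the *observed*
correlation converges to the stated target — the calibration tests check
this at $n = 20{,}000$ within $\pm 0.02$.

**What it does not emulate.** Marginals are independent apart from the
planted structure (no age–FVC decline gradient, no sex differences in
alcohol or muscle mass), spirometry values are truncated normals rather
than physiologically coupled (FEV1 can occasionally exceed FVC), there is
no attrition, no item non-response unless injected, and no reporting bias.
Passing tests therefore demonstrate that the algorithms recover known
structure under clean sampling assumptions — not that real checkup data
meet those assumptions.

**Randomness.** One global `set.seed(config$seed)` stream drives each
generator call, which makes identical configs byte-reproducible; we chose
this over per-subject counter-based streams (which would additionally make
subject subsets draw-stable) because base R has no counter-based generator
and reproducibility of the whole cohort is the property the pipeline needs.

## Network reporting choices

Significant edges are ranked by $|r|$ descending with lexicographic
tie-breaks on the canonical (sorted) pair, the user-supplied exclusion list
of well-established correlations is applied *before* truncating to the top
$k$ (default 250) — so removing a known association admits the next novel
one — and the DOT export writes nodes sorted by name and edges in rank
order with $|r|$ to four decimals as weight/label and the sign as a
separate attribute. Every output (CSV, TSV, DOT) uses fixed formatting so
repeated seeded runs are byte-identical.

## Problem sizes used by the test suite

The packaged tests exercise the pipeline at the scales the methods are
meant for while staying desk-fast: oracle-equivalence over 200 random
8-variable matrices; confounder-elimination over 100 replicates at
$n = 5000$; planted-edge recovery over 50 replicates of 20 variables at
$n = 2000$; attenuation detection over 100 and null calibration over 200
longitudinal replicates at $n = 1765$; and moment calibration at
$n = 20{,}000$. These sizes were chosen to keep Monte-Carlo error well
below the tested tolerances.

## Known limitations

* PCIT conditions on one variable at a time; jointly-acting confounders and
  latent variables pass through.
* Ordinal scoring (rank or band-mean) affects Pearson correlations; no
  rank-based option is provided because the screening contract is
  product-moment throughout.
* The correlation-ratio screen reports unsigned $\eta \in [0, 1]$; no sign
  convention is attached to categorical effect sizes.
* Pairwise-complete estimation can produce correlation matrices that are
  not positive semi-definite when missingness is heavy; PCIT uses the
  matrix as-is and the per-entry `n_pair` should be inspected.
* The exclusion list for "well-established" correlations is editorial
  input; the package applies it verbatim and records what was dropped.
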