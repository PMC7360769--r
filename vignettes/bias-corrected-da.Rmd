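---
title: "Bias-corrected differential abundance: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-corrected differential abundance: model, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfda)
```

## The problem and the model

Observed microbiome counts are a two-stage sample of an ecosystem: each
specimen captures an unknown, sample-specific fraction of the microbes in
a unit volume of the ecosystem (the *sampling fraction*, empirically
library size divided by microbial load). If group 1's specimens
systematically capture a larger fraction than group 2's, every taxon's
counts look shifted between groups even when nothing is differentially
abundant in the ecosystems. The package works on the log scale with the
offset model

$$y_{ijk} = d_{jk} + \mu_{ij} + \varepsilon_{ijk},
\qquad E(\varepsilon_{ijk}) = 0,$$

where $y_{ijk}$ is the natural log of the (zero-imputed) count of taxon
$i$ in sample $k$ of group $j$, $d_{jk}$ absorbs the sample's log sampling
fraction, and $\mu_{ij}$ is the log mean absolute abundance in the
ecosystem. Natural logs are used throughout; all test statistics are
invariant to the base, and effects/CIs are reported as natural-log fold
changes. Least squares over the two-way layout gives

$$\hat d_{jk} = \bar y_{\cdot jk} - \bar y_{\cdot j \cdot}, \qquad
  \hat\mu_{ij} = \bar y_{ij\cdot}.$$

$\hat d_{jk}$ averages over taxa, so it is accurate when the table is
reasonably wide (hundreds of taxa); its per-group mean is exactly zero,
which is why only *differences up to a group-level constant* of the
sampling fractions are identifiable. The per-taxon variance of
$\hat\mu_{ij}$ is estimated by the mean residual sum of squares

$$\hat\sigma^2_{ij} = \frac{1}{n_j^2}\sum_k
  (y_{ijk} - \hat d_{jk} - \hat\mu_{ij})^2,$$

with no degrees-of-freedom correction (the estimator is used on the scale
of the variance of a mean; at the sample sizes the method is intended for,
the $O(1/n)$ correction is immaterial — see the small-$n$ caveats below).

## Bias estimation by a Gaussian mixture

The naive difference $\Delta_i = \hat\mu_{i1} - \hat\mu_{i2}$ is centered
not at the true log fold change but at it *plus* the bias
$\delta = \bar d_{1\cdot} - \bar d_{2\cdot}$, which is common to all taxa.
Pooling across taxa, $\Delta_i$ is modeled as a three-component Gaussian
mixture: a null component centered at $\delta$ with variance
$\nu_{i0}^2 = \hat\sigma^2_{i1} + \hat\sigma^2_{i2}$, and down-/up-shifted
components centered at $\delta + l_1$ ($l_1 < 0$) and $\delta + l_2$
($l_2 > 0$) with variances $\nu_{i0}^2 + \kappa_r$, $\kappa_r \ge 0$. Two
notational ambiguities had to be resolved and are worth recording:

* $\nu^2$ is treated as a **variance** (it is defined as one), so the
  component densities use standard deviation $\sqrt{\nu_{i0}^2+\kappa_r}$;
  proper normal densities (with the $1/\nu$ Jacobian) are used in the
  E-step, because $\nu$ varies across taxa and the Jacobian does not
  cancel from the responsibility ratio.
* the "variance inflation" constraint is applied on the variance scale,
  $\nu_{ir}^2 = \nu_{i0}^2 + \kappa_r$, which guarantees non-null
  components are at least as dispersed as the null one.

Fitting is by a **generalized E-M**. The E-step is the standard
responsibility update. The M-step has no joint closed form (because
$\nu_{i0}^2$ varies by taxon), so it ascends blockwise: mixing
proportions (closed form), then the locations $(\delta, l_1, l_2)$ —
weighted normal equations solved with an active-set treatment of the sign
constraints, pinning a violated $l_r$ at 0 and pooling that component with
the null — then each $\kappa_r$ by bounded one-dimensional maximization.
Every block update is accepted only if it does not decrease the expected
complete-data objective, which makes the observed-data log-likelihood
provably non-decreasing; the trace is stored and asserted in the tests.

Numerical choices:

* **Initialization** (deterministic): $\delta^{(0)} = \mathrm{median}(\Delta)$,
  shifted components seeded from the tails below the 10th / above the 90th
  percentile, $\kappa^{(0)} = 0$. The median is robust to a moderate
  fraction of non-null taxa; the tail seeds only need to be on the correct
  side.
* **Convergence**: absolute log-likelihood change below `tol = 1e-5` or
  100 iterations. Non-convergence is a warning, not an error: near-flat
  likelihood ridges (e.g. when a shifted component is nearly empty) can
  make the last decimals of $l_r, \kappa_r$ drift for many iterations while
  $\hat\delta$ is stable to far better than the precision that matters
  downstream.
* **Classification**: taxa are assigned to the component with the largest
  responsibility; ties go to the null class, which is conservative because
  null taxa anchor $\delta$.
* **Degenerate inputs**: constant $\Delta$ collapses onto the null
  component with $\hat\delta = \Delta$; variances are floored at $10^{-12}$
  to keep densities finite; a component with zero mass keeps its previous
  location.

The companion weighted-least-squares estimator
$\hat\delta_{\mathrm{WLS}}$ is the precision-weighted mean of the
de-shifted $\Delta_i$ over the fitted classes, and its variance estimator
is the inverse summed precision — of order $1/(n\,m_0)$ with $m_0$ null
taxa, so the bias is essentially noiseless relative to any single taxon
once a few hundred null taxa are available. Both facts (near-perfect
correlation with the E-M estimate, and the $1/(n m_0)$ scaling within a
factor of two) are exercised in the test suite rather than merely stated.

## Testing

Two-group: $W_i = (\Delta_i - \hat\delta_{\mathrm{EM}})/
\sqrt{\hat\sigma^2_{i1}+\hat\sigma^2_{i2}}$, asymptotically N(0,1) under
the null. The variant $W_i^*$ subtracts $\hat\delta_{\mathrm{WLS}}$ and
adds its estimated uncertainty to the denominator, which algebraically
collapses to $\sqrt{\hat\sigma^2_{i1}+\hat\sigma^2_{i2}} +
\sqrt{\widehat{\mathrm{Var}}(\hat\delta_{\mathrm{WLS}})}$. The default
(`statistic = "auto"`) uses $W^*$ when $\min(n_1,n_2) < 30$ or when the
fitted non-null mass $\hat\pi_1 + \hat\pi_2$ exceeds 0.5 — a documented
heuristic for "not very large samples / many non-null taxa", overridable
by the user. Multiplicity is controlled by Bonferroni by default (Holm
and BH selectable); simultaneous confidence intervals use the
$z_{1-\alpha/(2m)}$ multiplier and the same denominator as the chosen
statistic, so an interval excludes 0 exactly when the Bonferroni-adjusted
test rejects.

Multigroup ($g \ge 3$): each non-reference group $j$ gets a pairwise bias
$\hat\delta_{rj}$ from its own E-M fit against the reference $r$ (restricted
to taxa testable in both groups of the pair); means and offsets are mapped
to the reference scale, pairwise statistics
$W_{i,jj'} = (\hat\mu^*_{ij}-\hat\mu^*_{ij'})/
\sqrt{\hat\sigma^2_{ij}+\hat\sigma^2_{ij'}}$ are formed, and the global
statistic is $\max_{j\ne j'} |W_{i,jj'}|$. Its null is simulated: per
draw, independent standard normals per pair combined with the same
max-of-absolute rule. Two deliberate choices: the absolute value is used
in **both** the observed and null statistics (the raw-max variant is
available behind `use_abs = FALSE`), and the p-value uses the strict
inequality as printed (an add-one correction avoiding exact zeros is
available behind `add_one = TRUE`). One null sample is shared across all
taxa with the same number of available pairs — the null depends only on
that count, and sharing cuts the cost from $B \times m$ to $B$ draws. The
residual variances are *not* recomputed after de-biasing: the transform
adds a constant per group, which leaves residuals unchanged.

## Zeros

Three kinds of zeros are distinguished. A taxon is declared
**structurally zero** (systematically absent) in group $j$ when its
presence proportion $\hat p_{ij}$ is 0 or when
$\hat p_{ij} - z\sqrt{\hat p_{ij}(1-\hat p_{ij})/n_j} \le 0$ (default
$z = 1.96$, exposed as `z_crit`). Differing structural-zero status between
two groups is itself evidence: the taxon is auto-declared differentially
abundant for that pair, reported with `decided_by_structural_zero = TRUE`
and the $p = 0$ convention, excluded from the bias estimation, and tested
only among the groups where it is present; taxa absent everywhere are
dropped. Remaining (**sampling**) zeros are replaced by a pseudo-count
(default 1, `pseudo_count`) on the raw count scale so logs are finite.
Outlier-zero detection is deliberately out of scope; the pseudo-count rule
is simple, documented and switchable, which keeps the core method
testable. Imputation happens before library-size considerations; the
choice is inconsequential for the statistics, which are invariant to
per-sample rescaling (asserted in the tests to 1e-10).

## The synthetic-data generator

`simulate_dataset()` draws, per taxon, a baseline ecosystem mean
$\theta_{i1} \sim U(50, 500)$; a fraction `prop_da` (default 0.1) of taxa
get $\theta_{i2} = \theta_{i1} e^{\pm u}$ with
$u \sim U(1, 2)$ and direction split 50/50 so the planted effects do not
themselves unbalance the microbial load. Sample-level abundances are
$A_{ijk} \sim \Gamma(\text{mean } \theta_{ij}, \text{shape } 2)$, log
sampling fractions $d_{jk}$ uniform over per-group ranges, and counts
$O_{ijk} \sim \mathrm{Poisson}(e^{d_{jk}} A_{ijk})$ — an overdispersed
Poisson-Gamma hierarchy whose moments are checked in the tests. The
presets realize three confounding regimes via the per-group $d$ ranges:
**large** (disjoint: $(-1.5,-0.5)$ vs $(-2.5,-1.5)$), **moderate**
(overlapping, shift 0.5) and **small** (identical). Zeros arise naturally
from the Poisson layer and exercise the zero-handling path.

What the generator does *not* emulate: inter-taxon correlation (taxa are
independent given the sampling fraction, matching the working-independence
assumption of the bias estimator but not real communities), taxonomic
structure, outlier zeros or contamination, and — importantly — the regime
in which *library sizes are balanced while microbial loads differ*. In the
presets, $d_{jk}$ is drawn independently of the load, so the library size
tracks the sampling fraction; a library-size normalization then removes
most of the group bias in these data, which it cannot do in the
balanced-library/unbalanced-load regime. Passing benchmarks on these
presets therefore demonstrates correct bias recovery and calibrated
testing under sampling-fraction confounding, not superiority over
library-size scaling in every regime real data can present.

`evaluate_fdr_power()` runs the full pipeline over replicates and scores
against the generator's truth; the benchmark conditions used by the
acceptance script are 100 replicates of $m = 500$, $n = (20, 30)$, 10% DA
taxa, large preset, Bonferroni at $\alpha = 0.05$. The test suite uses
problem sizes from $m = 50$ fixtures up to this benchmark scale, chosen so
the whole suite runs in a few minutes on one CPU.

## Known limitations

* **Very small groups.** With $n \approx 5{-}15$ per group and many
  low-abundance taxa, the pseudo-count imputation induces a per-taxon mean
  bias that does not shrink with $n$, and familywise-level tails of $W$
  are t-like rather than normal; false discoveries inflate. The method is
  intended for, and calibrated at, $n \gtrsim 20$ per group.
* **Simulated-null resolution.** The multigroup global test's smallest
  attainable p-value is $1/B$; with Bonferroni across $m$ taxa, $B$ must
  comfortably exceed $m/\alpha$ or discreteness alone will produce
  rejections. The default $B = 1000$ suits exploratory use; for strict
  familywise control at large $m$, increase `B` (the shared-null design
  makes this cheap).
* **Majority-differential communities.** When well over half the taxa are
  differential in the same direction, the null mixture component no longer
  anchors $\delta$ and the bias estimate degrades (the `auto` statistic
  already switches to $W^*$ when the fitted non-null mass exceeds 0.5).
* **Covariates and repeated measures** are out of scope; the design is a
  single categorical factor.
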