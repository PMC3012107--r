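---
title: "SGoF multiple testing and the SGoFicance Trace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SGoF multiple testing and the SGoFicance Trace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgoftrace)
```

## The model

Given S simultaneous tests with p-values $p_1, \dots, p_S$, SGoF asks a
population-level question: do *more* p-values fall at or below a working
threshold $\gamma$ than the intersection null (all S nulls true,
p-values i.i.d. Uniform(0,1)) would produce? The observed count
$K(\gamma) = \#\{p_i \le \gamma\}$ is Binomial$(S, \gamma)$ under that null,
so the meta-test p-value is the exact upper tail
$P(\mathrm{Bin}(S,\gamma) \ge K(\gamma))$, and the rejection region
$K \ge b_\alpha(\gamma)$ uses the critical count

$$b_\alpha(\gamma) = \min\{b : P(\mathrm{Bin}(S,\gamma) \ge b) \le \alpha\}.$$

Rejection controls the family-wise error rate at $\alpha$ **in the weak
sense only**: the guarantee holds under the complete null, not under
arbitrary mixtures. Upon rejection the $N_\alpha(\gamma) = K - b + 1$
smallest p-values are declared effects; the step-down narrative (decrement
$K$ and re-test until significance is lost) yields exactly the same count,
and `sgof_sequential()` exists purely to cross-validate that identity.

Three derived quantities accompany a declaration set:

* the realized threshold $q_\alpha(\gamma)$, the $N$-th order statistic of
  the p-values;
* $\hat\pi_0$, the estimated proportion of true nulls, computed as the mean
  of $-\log(1 - p_i)$ — for Uniform(0,1) p-values each summand is a
  standard exponential with mean 1, while genuine effects concentrated near
  zero pull the average down;
* the plug-in FDR estimate $\mathrm{eFDR} = S\, q_\alpha(\gamma)\,
  \hat\pi_0 / N_\alpha(\gamma)$: expected null count below the threshold
  over declared count.

The **SGoFicance Trace** evaluates all of this on a $\gamma$ grid and plots
the log meta-p-value, $N_\alpha(\gamma)$, eFDR and $q_\alpha(\gamma)$ as
panels A–D. $N_\alpha(\gamma)$ is typically an inverted U: both $K$ and
$b$ grow with $\gamma$, and their difference peaks at an interior value.

## Tunable parameters

* `gamma` (working threshold, unitless probability; classical choice 0.05).
  Power varies strongly with it, which is the trace's raison d'être. In the
  bundled simulation scenario with 10% effects of size $w = 2$, power peaks
  near $\gamma \approx 0.09$.
* `alpha` (weak-FWER level, default 0.05). The trace's maximum eFDR is
  empirically insensitive to it, so the default is a good first choice.
* `capped` (default `FALSE`). Because the procedure tests the full p-value
  distribution, the realized threshold $q_\alpha(\gamma)$ can exceed
  $\alpha$ when $\gamma > \alpha$. Users unwilling to declare any p-value
  above $\alpha$ can set `capped = TRUE`, which applies
  $N = \min(K - b + 1, K(\alpha))$ and preserves weak FWER control.
* `gamma_grid` (default `seq(0.01, 0.99, 0.01)`): "γ varying continuously
  over (0,1)" realized as a configurable finite grid; 99 points keep the
  trace smooth at negligible cost.

## Numerical choices

* **Exact binomial arithmetic.** Tails come from `pbinom(..., lower.tail =
  FALSE)` (stable survival-function evaluation), never a normal
  approximation — S in the thousands is routine. The test suite checks
  `binomial_critical_value()` and `meta_test_pvalue()` against a brute-force
  pmf-summation oracle for every $S \le 60$ over a $\gamma \times \alpha$
  grid.
* **Boundary at $P = \alpha$.** The rejection rule is $\le$: a meta-test
  p-value exactly equal to $\alpha$ rejects (consistent with the definition
  of $b_\alpha$). Floating point can return such a tail as $\alpha$ plus one
  ulp, so tail–$\alpha$ comparisons carry a $10^{-9}$ relative guard; the
  test oracle applies the same rule.
* **Degenerate cases.** $K < b$ clamps $N$ to 0, with threshold and eFDR
  reported as absent (`NA`). $K = 0$ gives a meta p-value of exactly 1.
  Underflowing tails are floored at $10^{-300}$ so the log-significance
  panel stays finite.
* **Ties.** The defining relation $N = \#\{p_i \le q\}$ has no solution when
  p-values tie at the cut; $N$ stays authoritative, $q$ is the $N$-th order
  statistic, and `achieved_count` reports $\#\{p_i \le q\}$ so the
  discrepancy is visible. Among tied p-values, declared effects keep input
  order (stable sort) for determinism.
* **$\hat\pi_0$ edge cases.** $p = 1$ would make $-\log(1-p)$ infinite; such
  values are clamped to $1 - 10^{-15}$ with a warning rather than dropped
  (dropping would silently change S). The raw estimate may exceed 1 and is
  reported as is; eFDR truncates it at 1 internally, and eFDR itself is
  clipped into [0, 1].
* **Natural log** in panel A; the reference line sits at $\log(\alpha)$
  ($\approx -3.00$ for $\alpha = 0.05$). The base only shifts the scale.
* **Ties in the trace summary** resolve to the *smallest* $\gamma$ attaining
  the maximum $N$: equal power at a stricter realized threshold.

## The synthetic-data generator

`generate_pvalues(S, effect_proportion, w)` emulates a one-sided normal
test: exactly `round(S * effect_proportion)` effects draw
$p = 1 - \Phi(Z + w)$ with $Z \sim N(0,1)$ — $w$ is the true standardized
shift, in standard-error units — and the rest are Uniform(0,1) nulls. The
effect count is deterministic per trial, and one sample per trial is shared
by every method under comparison. This matches the published simulation
design it reproduces, but real data differ in ways the generator does not
emulate: tests are correlated (co-regulated genes), effect sizes are
heterogeneous rather than a single $w$, and p-values from discrete or
composite tests are not exactly uniform under the null. Passing simulation
tests therefore validate the procedure's arithmetic and its operating
characteristics under independence, not its behaviour under dependence.

In the Monte-Carlo summaries, "FDR" is the per-trial false-discovery
proportion $\mathrm{FP}/\max(R, 1)$ averaged over trials (the truth is known
in simulation), not the eFDR plug-in estimate; the $\max(R,1)$ denominator
is the standard convention for trials with no rejections. The
Benjamini–Hochberg baseline uses `stats::p.adjust(method = "BH")`, whose
declaration set `padj <= q` is exactly the step-up rule; an independently
hand-written step-up serves as its cross-check in the tests. Per-trial RNG
substreams are derived deterministically from the run seed, so any single
trial is reproducible in isolation.

## Problem sizes and reproducibility

The test suite runs the Monte-Carlo checks at 200 trials of S = 1000 with
tolerances of $\pm 0.04$ (about eight Monte-Carlo standard errors), and weak
FWER control under the complete null at 2000 trials; `scripts/acceptance.R`
reproduces the full study at 1000 trials per scenario, seeded entirely from
its `--seed` argument. Reducing trial counts scales Monte-Carlo error as
$1/\sqrt{n}$, and every summary carries standard errors so principled
tolerances can be derived.

Two properties of null data are worth knowing when reading trace output.
First, at any fixed $\gamma$ the probability of declaring anything is at
most $\alpha$, so on average at least $1 - \alpha$ of grid points of a null
trace are empty — but the exceptional trials reject over a contiguous band
of $\gamma$, so a *single* null trace occasionally shows a long non-empty
stretch. Second, the trial-averaged meta p-value on null data hovers near
0.5 across the grid, rising somewhat as $\gamma \to 1$ where the binomial
becomes very discrete; the sharply increasing log-significance curve
described for typical applications is a feature of data containing effects.

## Design decisions at genuinely open points

* The "$100(1-\alpha)\%$ percentile" defining the critical count is
  ambiguous for a discrete distribution; we take the smallest $b$ with tail
  $\le \alpha$, the conservative side that makes the weak-FWER claim hold
  exactly.
* The closed form $K - b + 1$ with S held fixed is treated as normative for
  the sequential algorithm (the step-down loop re-tests with the same S).
* $\hat\pi_0$ is implemented as the plain mean of $-\log(1-p_i)$, as the
  method is verbally defined; no additional correction factor is applied.
* The uncapped count is the default and is what the simulation framework
  scores; the cap is an optional, more conservative variant.
* Automatic selection of a single optimal $\gamma$ is deliberately out of
  scope: the trace is the deliverable, and the choice is left to the
  analyst's power/FDR trade-off.

## Known limitations

* Weak FWER control only; no strong control, and no per-hypothesis adjusted
  p-values in the Bonferroni/Holm sense.
* Independence of tests is assumed throughout; under strong positive
  dependence the binomial null is misspecified and the meta-test can be
  anticonservative.
* $\hat\pi_0$ by the mean of $-\log(1-p)$ is simple and conservative;
  alternative estimators (and the q-value machinery) are intentionally not
  implemented.
* The eFDR is a plug-in estimate, not a controlled quantity: SGoF fixes
  $\alpha$, and the FDR it "pays" is reported, not prescribed.
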