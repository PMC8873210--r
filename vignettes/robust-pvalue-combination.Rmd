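---
title: "Robust combination of dependent p-values: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust combination of dependent p-values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robcomb)
```

## The problem

Given $k$ p-values $P_1, \dots, P_k$, each testing an individual null
hypothesis, we want a single test of the global null
$H_0 = \bigcap_i H_{i,0}$ that remains valid when the joint dependence of
the $P_i$ is unknown — the situation of gene- and set-based association
tests in genomics, and of meta-analyses where directional (one-sided)
p-values from the same studies must be pooled. Under $H_0$ each
$P_i \sim U(0,1)$, but nothing is assumed about their joint law.

## The tests

**Cauchy combination test (CCT).** Each p-value is mapped to the standard
Cauchy scale, $T_i = \tan[(0.5 - P_i)\pi]$, and the statistic is the
weighted sum $T = \sum_i w_i T_i$ with $w_i \ge 0$, $\sum_i w_i = 1$. The
combined p-value is the upper-tail Cauchy probability
$p_{CCT} = \Pr[\mathcal{C}(0,1) \ge t]$. Under independence $T$ is
*exactly* standard Cauchy for any weights, so $p_{CCT}$ is exactly
uniform; under arbitrary dependence the Cauchy tail still bounds the
rejection probability as the significance level shrinks, because
$\Pr[T \ge t] \le k \Pr[\mathcal{C}(0,1) \ge t]$ for any joint law and
the Cauchy tail is heavy enough that the factor $k$ washes out in the
limit.

Two structural facts shape everything else in this package:

1. *Bracketing:* since $T_{(1)} \ge T \ge T_{(k)}$ for the ordered
   transforms, $P_{(1)} \le p_{CCT} \le P_{(k)}$ — CCT can never return
   stronger evidence than its strongest input. It is therefore a poor
   choice for combining independent p-values, where Fisher's chi-square
   ($X^2 = -2\sum \ln P_i$ on $\chi^2_{2k}$) or Stouffer's z
   ($Z = \sum \Phi^{-1}(1-P_i)/\sqrt{k}$) can go far below the minimum.
2. *Powerlessness on complementary pairs:* if $p_1 + p_2 = 1$ (e.g. the
   left- and right-sided p-values of the same statistic), the transforms
   cancel, $T = 0$, and $p_{CCT} = 0.5$ regardless of how extreme the
   pair is. CCT then has zero power at any level below 0.5, while the
   MinP test of the same pair reduces exactly to the two-sided test.

**MinP.** The minimum p-value calibrated by Šidák,
$1 - (1 - P_{(1)})^k$ (exact under independence), or Bonferroni,
$\min(1, k P_{(1)})$ (valid under any dependence). Robust but
conservative when the p-values are strongly dependent.

**MCM and CMC.** The two-stage tests apply *both* CCT and MinP to the
same input and then combine the two (dependent) results:
$$p_{MCM} = 2\min\{p_{CCT},\, p_{MinP},\, 0.5\}, \qquad
  p_{CMC} = CCT\{p_{CCT},\, p_{MinP}\}.$$
MCM is a Bonferroni (MinP) combination of the two first-stage tests, CMC
an equal-weight CCT of them. Both inherit small-level type-I control
from their components under arbitrary dependence, track CCT's power when
small p-values reinforce each other, and retain MinP's power where CCT
is weak — at the price of MCM's two-fold penalty, visible as type-I
ratios near 0.5 under well-calibrated conditions.

```{r}
p <- c(0.99, 0.001, 0.6)
combine_pvalues(p)
```

## MinP calibration: which formula where

No single MinP variant fits every context, and the choice is exposed
everywhere as `minp_mode`:

* the plain MinP test and the stage-1 (independent studies) combiner
  default to **Šidák**, which is exact under independence;
* the inner MinP of MCM/CMC and the stage-2 (dependent pair) combiner
  default to **Bonferroni**, the bound that stays valid under the strong
  dependence between $p_{CCT}$ and $p_{MinP}$ — and the form the MCM
  definition $2\min\{\cdot\}$ itself uses.

Both variants are nearly identical at small levels; the defaults are the
internally consistent choice, and every result records the mode used.

## Numerical choices

* **Cauchy transform.** $\tan[(0.5-p)\pi]$ is evaluated directly only
  for $p \in [0.25, 0.75]$. Outside that band the argument $0.5 - p$
  cannot carry the low-order bits of $p$, so the algebraically identical
  cotangent forms $1/\tan(p\pi)$ (for $p < 0.25$) and $-1/\tan((1-p)\pi)$
  (for $p > 0.75$; $1-p$ is exact there) are used instead. The relative
  error stays within a few ulp down to $p = 10^{-300}$, and a lone tiny
  p-value round-trips through CCT to relative error well under $10^{-6}$.
* **Boundary p-values.** $p = 1$ has a transform of $-\infty$; inside
  CCT (and the second stage of CMC) it is clipped to $1 - 10^{-15}$, the
  limit convention under which, e.g., $CCT\{1, 0.5\} \to 1$. $p = 0$ is
  rejected everywhere with a domain error: a zero p-value has already
  falsified the global null, and silently accepting it would hide
  upstream underflow.
* **Weights** are normalized to sum to one; all-zero or negative weights
  are errors. The CMC second stage always uses equal weights on its pair.
* **Upper-tail evaluation** goes through `pcauchy(..., lower.tail =
  FALSE)`, which computes small tails as $\arctan(1/t)/\pi$ without
  cancellation.
* **Reporting.** All computation is double precision end to end;
  rounding happens only in printing. This matters for the two-stage
  tests: the second Cauchy stage amplifies rounding of its inner pair,
  so e.g. re-rounding stage-1 values to 4 decimals can move a CMC
  p-value from 0.22 to 0.25.

## The correlation models and the simulation machinery

Three structured correlation matrices drive the Monte-Carlo experiments:

* **expo** — AR(1), $\sigma_{ij} = \rho^{|i-j|}$, $\rho \in [0,1)$;
* **poly** — polynomial decay, $\sigma_{ij} = 1/(0.7 + |i-j|^r)$ off the
  diagonal, $r > 0$. Positive definiteness is not guaranteed by the
  formula for every $(k, r)$, so the spectrum is checked at construction
  and a negative eigenvalue is a loud failure, never a silent repair;
* **sig** — a deliberately singular model: $A$ is the $(k/5) \times k$
  matrix with $a_{ij} = d^{|i-j|}$, and $\Sigma$ is $A^{\top}A$
  normalized to unit diagonal, giving rank exactly $k/5$. For $k = 5$
  the construction collapses to the all-ones matrix (every z-score is
  the same variable); this is the formula taken literally, and worth
  knowing when interpreting results at small $k$.

Sampling always goes through one code path: a symmetric
eigendecomposition factor $B$ with $B^{\top}B = \Sigma$, with
eigenvalues within $10^{-8}\lambda_{\max}$ of zero clipped to zero.
Cholesky would fail on the singular model; the eigenfactor handles all
three, and for the `sig` model it also fixes the factor's row count at
the true rank.

`estimate_rejection_rates()` draws $X \sim MVN(\mu, \Sigma)$, forms the
left-sided $\Phi(X_i)$, right-sided $1 - \Phi(X_i)$ and two-sided
$2\Phi(-|X_i|)$ p-values per coordinate, applies the selected tests per
replicate, and reports, per (test, side, level): the rejection
proportion, its ratio to the level, and the binomial standard error.
Design details fixed once and documented:

* *Rejection rule* is $p \le \alpha$ (inclusive).
* *Blocking.* Replicates are processed in fixed blocks of $10^5$, each
  block seeded deterministically from (seed, block index). Memory stays
  bounded (about 80 MB per block at $k = 100$) and results are
  bit-identical however many replicates are requested beyond a block
  boundary — the block, not the run, is the reproducibility unit.
* *Effect placement.* Under the alternative, `n_significant`
  coordinates receive mean $\pm\mu$ (the first `n_negative` of them
  negative). Which coordinates are shifted matters under structured
  $\Sigma$, and nothing in the model pins it down, so placement is an
  explicit config field — `head` (first indices, the deterministic
  default), `spread`, or `random`.

### What the generator does and does not emulate

The generator reproduces the study conditions the tests were designed
for: Gaussian z-scores with the three structured correlation models,
one- and two-sided p-values, mean shifts of a few standard deviations.
It does **not** emulate non-Gaussian test statistics, estimated
(noisy) correlation, differing per-study sample sizes, or p-values that
are discrete or conservative to begin with. A calibration ratio of 1.16
under the AR(1) model says exactly that — no more; real GWAS-scale
dependence can be harsher than any of the three models.

Default experiment sizes: the packaged null-calibration grid runs the
three models at $k \in \{5, 10, 20, 100\}$ with $10^6$ replicates per
config — enough to resolve a type-I ratio at $\alpha = 0.05$ to about
$\pm 0.004$ (one binomial SE). Exploratory runs at $10^4$–$10^5$
replicates reproduce the same patterns with proportionally wider error
bars; the test suite uses those sizes.

## The meta-analysis workflow

For a published table of per-study odds ratios with 95% CIs, the
z-score is recovered from the CI width: the half-width of the log-OR CI
is $1.96\,SE$, so
$$z = \frac{\ln OR}{\ln(U/L)/3.92}.$$
An alternative reading that replaces $\ln OR$ by the CI midpoint
$\ln(UL)/2$ is provided (`formula = "midpoint"`); the two coincide when
the published interval is symmetric around the published OR on the log
scale and differ only through rounding of the published numbers. The
default is the log-OR form, which reproduces the per-study p-values of
the packaged 12-study table to all four printed decimals.

```{r}
res <- run_meta_pipeline(geriatric_rehab())
res$stage2
```

Stage 1 combines the independent studies per direction (left, right,
two-sided) with MinP/Šidák, Fisher, and Stouffer. Stage 2 combines each
method's dependent (left, right) pair with CCT, MinP/Bonferroni, MCM and
CMC, always from the unrounded stage-1 values. The Stouffer pair sums to
one by construction, so its stage-2 CCT is 0.5 to within round-off —
the powerless configuration made concrete — while MCM and CMC still
recover the signal carried by the right-sided combination.

## Known limitations

* The type-I guarantees of CCT, MCM and CMC are asymptotic in the
  significance level; at $\alpha = 0.05$ CCT runs measurably liberal
  under positive dependence (ratios around 1.1–1.2 in the AR(1) model),
  and the package makes no small-$\alpha$ correction.
* MCM's doubling makes it conservative (ratios near 0.5–0.6) whenever
  its two components are themselves calibrated.
* The `sig` model at $k = 5$ is degenerate by construction (all-ones);
  conclusions drawn from it describe a single underlying variable.
* Power for the figure-style experiments is reported as raw empirical
  rates; the package deliberately does not attempt to match any
  particular published power curve, only the qualitative orderings
  (e.g. MinP above CCT for one-sided p-values with mixed effect
  directions), which the test suite checks.
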