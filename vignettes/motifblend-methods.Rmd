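---
title: "Blended generative-discriminative training of PWM classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blended generative-discriminative training of PWM classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifblend)
```

## The model

motifblend classifies fixed-length DNA sequences ($L$-mers over
$\{A,C,G,T\}$) as transcription factor binding sites (foreground) or
genomic background. The classifier is naive Bayes with one position
weight matrix (PWM) per class: class $c \in \{\mathrm{bg},
\mathrm{fg}\}$ has probability $P(c\mid\lambda)$ and emits a sequence
$x = (x_1,\dots,x_L)$ with probability

$$P(x \mid c, \lambda) \;=\; \prod_{l=1}^{L} \theta^{(c)}_{l,\,x_l},$$

where each PWM column $\theta^{(c)}_{l,\cdot}$ is a probability vector
over the four nucleotides. A sequence is called a site when the log
joint ratio

$$s(x) \;=\; \log\frac{P(\mathrm{fg}\mid\lambda)\,
P(x\mid \mathrm{fg},\lambda)}{P(\mathrm{bg}\mid\lambda)\,
P(x\mid \mathrm{bg},\lambda)}$$

is strictly positive; the posterior site probability is
$\mathrm{plogis}(s(x))$. Ties at $s(x)=0$ go to the background, the
conservative call for a rare-positive detection task.

All simplex-constrained groups (the class pair and every PWM column of
both classes) are stored as unconstrained reals through the softmax map
$\theta_a = e^{z_a}/\sum_b e^{z_b}$, evaluated with a max-shift so that
$|z|$ up to several hundred cannot overflow. The parameterization is
over-parameterized on purpose: adding a constant to a group's $z$ does
not change $\theta$ (a flat "gauge" direction), the objective is
invariant along it, and the quasi-Newton optimizer handles the flat
direction without gauge fixing. This keeps the gradient algebra simple;
identifiability lives at the $\theta$ level, which is what all results
report.

## One objective, six learning principles

Given labeled training data $(C, D)$, the package maximizes a single
blended objective over the full parameter vector $\lambda$:

$$\mathcal{O}_\beta(\lambda) \;=\;
\beta_0 \log P(C \mid D, \lambda) \;+\;
\beta_1 \log P(C, D \mid \lambda) \;+\;
\beta_2 \log Q(\lambda \mid \alpha),$$

with nonnegative weights $\beta = (\beta_0,\beta_1,\beta_2)$ summing
to 1. The three terms are the conditional likelihood of the labels
(discriminative), the joint likelihood of labels and sequences
(generative), and a Dirichlet-type prior. Classical estimators are
corners or edges of this simplex:

| principle | $\beta$ |
|---|---|
| maximum likelihood (ML) | $(0, 1, 0)$ |
| maximum a posteriori (MAP) | $(0, 0.5, 0.5)$ |
| maximum conditional likelihood (MCL) | $(1, 0, 0)$ |
| maximum supervised posterior (MSP) | $(0.5, 0, 0.5)$ |
| generative-discriminative trade-off (GDT) | $\beta_2 = 0$ line |
| penalized trade-off (PGDT) | $\beta_2 = 0.5$ line |

`beta_for_principle()`, `gdt_beta()` and `pgdt_beta()` construct these;
`beta_weights()` renormalizes arbitrary nonnegative weights while
preserving exact zeros so the limiting cases stay exact identities, not
approximations. For the GDT family we take $\gamma = 1$ to be the ML
end and $\gamma = 0$ the MCL end, mirroring the penalized family
(MAP/MSP); the two families differ only in whether the prior weight is
0 or 0.5.

Two algebraic readings of the simplex are implemented and tested as
exact identities:

* **Axis / line reading** (`pgdt_canonical()`, `virtual_ess()`). Any
  point with $\beta_0 + \beta_1 > 0$ equals, after dividing by
  $\beta_0+\beta_1$, a penalized trade-off with
  $\gamma = \beta_1/(\beta_0+\beta_1)$ and the prior raised to the
  power $\xi = \beta_2/(\beta_0+\beta_1)$. Because the prior family is
  closed under powering (below), raising it to $\xi$ is the same prior
  with every pseudo-count scaled by $\xi$ — a "virtual" equivalent
  sample size $\xi \cdot \mathrm{ESS}$. A point such as
  $\beta=(0.05,0,0.95)$ is therefore plain MSP estimation with virtual
  ESS $76$ when the original foreground ESS is 4.
* **Weighted-posterior reading**
  (`effective_posterior_hyperparams()`). The generative and prior
  terms together are the kernel of a product-Dirichlet with
  pseudo-counts $\tilde\alpha = \beta_1 n + \beta_2 \alpha$ ($n$ the
  sufficient counts), so every simplex point is supervised-posterior
  estimation under a data-informed prior. The composition is computed
  for any $\beta$; the probabilistic interpretation strictly requires
  positive weights, which the documentation notes.

## The prior and its conventions

The prior is a product over all simplex groups. On the unconstrained
parameterization we use, for a group with pseudo-counts $\alpha$,

$$\log q(z) \;=\; \sum_a \alpha_a \log \theta_a(z) \;-\; \log Z(\alpha),
\qquad
Z(\alpha) = \frac{\prod_a \Gamma(\alpha_a + 1)}
{\Gamma\!\left(\sum_a \alpha_a + K\right)}.$$

The kernel exponent is $\alpha_a$, not the $\alpha_a - 1$ of the
density on the simplex: the softmax change of variables contributes
exactly one extra factor of $\prod_a \theta_a$, and folding it into the
exponent has two consequences we rely on:

1. **Power closure.** $\xi \log q_\alpha(z) = \log q_{\xi\alpha}(z) +
   \text{const}$ exactly, for any $\xi > 0$ — the identity behind the
   virtual-ESS reading. The suite checks that the difference has
   variance $< 10^{-16}$ over random parameter points.
2. **Pseudo-count closed form.** On the generative edge ($\beta_0 =
   0$) the objective decouples over groups and its exact maximizer is
   $\theta_a = (\beta_1 n_a + \beta_2 \alpha_a) / (\beta_1 N +
   \beta_2\,\mathrm{ESS})$ — relative frequencies at ML, the familiar
   posterior-mean estimator $(n_a + \alpha_a)/(N + \mathrm{ESS})$ at
   MAP.

Hyperparameters are specified through per-class equivalent sample
sizes: each PWM column of class $c$ gets $\alpha = \mathrm{ESS}_c
\cdot q$ with uniform base distribution $q$ ("uniform pseudo data"),
and the class group gets $(\mathrm{ESS}_{bg}, \mathrm{ESS}_{fg})$.
Defaults are ESS 4 for the foreground and 1024 for the background,
reflecting the orders-of-magnitude difference between the number of
curated sites and background windows in a typical binding-site study.
The choice of giving the class group the pair of class ESS values is a
convention; any fixed positive pair only shifts the fitted class odds
slightly and identically across simplex points.

## Training

* $\beta_0 = 0$: closed form, exact (used by default; `method =
  "numeric"` forces the optimizer and is how the corner-equivalence
  tests exercise both paths).
* $\beta_0 > 0$: limited-memory quasi-Newton ascent (L-BFGS-B) on the
  packed unconstrained vector, with the exact analytic gradient. Per
  group with log-probability weights $w$ the gradient is $w_a -
  \theta_a \sum_b w_b$; for the conditional term the weights are
  posterior residuals $\mathbb{1}[c_i = c] - P(c \mid x_i, \lambda)$
  accumulated per position and symbol. The gradient is validated
  against central finite differences ($h = 10^{-6}$) on fixtures small
  enough that the $|f|\,\varepsilon/2h$ cancellation error stays below
  the $10^{-6}$ assertion.

Initialization is the closed form at $(0, \max(\beta_1, 10^{-3}),
\max(\beta_2, 10^{-3}))$: a smoothed generative warm start that is
strictly interior even for pure ML (where zero counts would otherwise
put the start on the boundary). Convergence is declared on a gradient
max-norm below `tol` ($10^{-6}$) or a relative objective change below
$10^{-9}$ (`factr` in L-BFGS-B terms), with `max_iter` 1000. The
conditional term is not concave in this parameterization, so global
optimality is not guaranteed in general; in practice the generative
warm start lands in the right basin on every fixture we test, and on
non-separable data the MCL corner reproduces the optimum of a
(concave) logistic regression on one-hot position encodings, which the
suite asserts to $10^{-3}$ —
the two-PWM conditional likelihood is exactly a logistic function of a
linear score in those features. On linearly separable data the MCL/GDT
corner diverges like logistic regression does; any positive prior
weight removes the divergence.

## Evaluation protocol

`holdout_evaluate()` repeats, `repeats` times: a stratified 90/10
train/test split, training at the given $\beta$, scoring of the
held-out side, and the performance measures. The headline measure is
**sensitivity at fixed specificity** (default 99.9%): with $m$
held-out negatives, $k = \lfloor (1-\mathrm{spec})\, m \rfloor$ false
positives are allowed, the threshold is the $(k+1)$-th largest negative
score, and sensitivity is the fraction of positives strictly above it.
This matches brute-force enumeration over all thresholds, which the
suite verifies on random score sets. ROC-AUC (rank form, ties counted
half), the trapezoidal area under the precision-recall curve (anchored
at recall 0, precision 1), and the classification rate at threshold 0
are reported alongside.

Three protocol details matter:

* **Split units.** Foreground sites are split individually; the
  background is split at the level of chunks (pieces of at most 100
  bp), and overlapping $L$-windows are extracted within each side.
  Splitting windows directly would place near-duplicate 16-mers from
  the same chunk on both sides of the boundary.
* **Pairing.** `simplex_scan()` draws the sequence of repeat seeds
  once and reuses it at every grid point, so every $\beta$ sees the
  identical train/test partitions and comparisons across the simplex
  are paired.
* **Determinism.** All randomness flows from one seed; reruns are
  bitwise identical.

`simplex_scan()` evaluates the grid $\{(\beta_0,\beta_1):
\beta_0,\beta_1 \ge 0 \text{ multiples of } s,\ \beta_0+\beta_1 \le
1\}$ (231 points at $s = 0.05$) and `autoplot()` renders the standard
$(\beta_0,\beta_1)$-projection heatmap.

## The synthetic benchmark

`make_benchmark()` emulates the classical study design so the entire
pipeline is testable without restricted motif databases: `n_fg` sites
of length $L$ sampled from a foreground PWM, plus an i.i.d. (order-0)
background of `bg_total_bp` residues emitted as chunks of at most
`chunk_len` bp. Defaults mirror the scale of a curated binding-site
collection: 104 sites of length 16 against 68,141 bp of background in
100 bp chunks, foreground/background ESS 4/1024. The default motif
(`motif_pwm()`, consensus probability 0.7 per column) carries roughly
10 bits of information, a realistic figure for a vertebrate
transcription factor.

What the generator does *not* emulate — and hence what green tests do
not certify about real data: positional dependence within sites,
higher-order background composition (CpG depletion, repeats), motif
instances hidden inside the background, reverse-strand sites, and
curation biases of real site collections. On this well-specified
generator the generative corner is typically the best point of the
simplex (the model family contains the truth); the interior advantage
reported for real site collections arises from model misspecification,
which the generator deliberately lacks.

## Null calibration

If foreground and background are drawn from the same distribution, a
calibrated protocol should read back sensitivity $\approx
1-\mathrm{specificity}$. Two statistical subtleties shape how the
package tests this at specificity 99.9%:

* **Independent negatives.** The threshold calibration
  $E[\text{sensitivity}] = (k+1)/(m+1)$ holds for exchangeable,
  independent scores. Overlapping windows violate it in a systematic
  direction: top scores arrive in runs of overlapping windows, the
  $(k+1)$-th largest negative is inflated, and the null sensitivity is
  conservative. The null check therefore uses background chunks of
  exactly $L$, i.e. non-overlapping windows.
* **Independent pools.** With one finite foreground pool recycled
  across repeats, the repeat mean converges to a pool-dependent value:
  at specificity 99.9% only about $0.002\,n_{fg}$ pool members are
  "tail-capable", so the across-repeat standard error wildly
  understates the pool-level sampling noise and the check would be a
  coin flip over pools at any scale. The null check therefore pools
  200 repeats from 20 independently generated null benchmarks (300
  sites and 50,000 background 16-mers each), for which the
  across-repeat standard error is a fair uncertainty.

## Problem sizes and numerical choices in the shipped checks

The test suite and `scripts/acceptance.R` run on synthetic data sized
for completeness of coverage rather than maximal realism: corner
equivalences on a 200-sequence set; gradient checks on ~180 sequences
at $L=4$; protocol determinism and pairing at 50 repeats on a 60-site
/ 4 kb benchmark; the acceptance scan at grid step 0.25 with 25
repeats on a 104-site / 8 kb benchmark; recovery from 10,000 sampled
16-mers; the null calibration as described above. Degenerate inputs
follow fixed conventions: probability zero entries give $-\infty$ log
densities rather than errors, positions impossible under both classes
contribute zero to a score, ties in ROC ranks count one half, and
score ties at the decision threshold go to the background.

## Limitations

Two classes only; forward strand only; PWMs only (no positional
dependence or higher-order background models); no score calibration
beyond the built-in posterior; no statistical comparison machinery
between simplex points beyond the paired design. The simplex scan
retrains at every grid point and repeat, so full 231-point scans at
1000 repeats are compute-intensive at interior points; the generative
edge is closed-form and fast.
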