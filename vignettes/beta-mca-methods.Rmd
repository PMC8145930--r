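---
title: "Maximal-causes models for Beta-distributed interval data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximal-causes models for Beta-distributed interval data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betamca)
```

## The model

`betamca` fits latent variable models for observations that live on a
bounded severity scale — graded medical symptom descriptors in
\[0, 1\], rescaled pixel intensities, and similar interval data.  The
natural observation family on the open unit interval is the Beta
distribution, and unlike the Bernoulli or Poisson families used by
classical disease–symptom Bayes nets, a Beta observable carries *two*
degrees of freedom: a mean and a variance.  A latent-cause model for
interval data therefore has to specify how active causes combine to
set both.

The model has `H` binary causes $s_h \sim \text{Bernoulli}(\pi_h)$
plus an always-active background cause $s_0 = 1$.  Each cause carries
two dictionary columns, the *mean-value parameters*
$W_{dh} = \mathbb{E}[\log y_d]$ and $V_{dh} = \mathbb{E}[\log(1-y_d)]$
of its Beta distribution for observable $d$.  From $(W, V)$ the
natural (shape) parameters follow through the inverse of the digamma
relations

$$ w_1 = \psi(\eta_1) - \psi(\eta_1 + \eta_2), \qquad
   w_2 = \psi(\eta_2) - \psi(\eta_1 + \eta_2), $$

and from the shapes the mean dictionary $M(\Theta)$ and variance
dictionary $\Sigma^2(\Theta)$ follow in closed form.  Causes combine
through a **maximum non-linearity**: for each observable $d$ the
single active cause with the largest mean entry,
$h(d, s, \Theta) = \arg\max_h \{ s_h M_{dh} \}$, determines the whole
observation distribution — its mean *and* its variance.  The
background guarantees a well-defined distribution when no cause is
active and models healthy-patient (or empty-image) statistics.  This
is the maximal-causes superposition: a severe, low-variability disease
that dominates a symptom should also dominate that symptom's
variability, regardless of what milder co-occurring causes would
contribute.

Two model families are implemented:

* `em_fit()` — the full model with per-cause mean *and* variance
  dictionaries (`W`, `V`);
* `em_fit_scalar_variance()` — the restricted variant with one mean
  dictionary and a single shared variance $\sigma^2$, the natural
  baseline for judging what individual variance fields add.

## Training

Training maximizes the free energy (ELBO) by EM.  The E-step either
enumerates all $2^H$ states exactly (guarded by `enum_cap`, default
15) or maintains per-data-point subsets $K^{(n)}$ of states with
*truncated posteriors* — the exact posterior renormalized on
$K^{(n)}$.  The subsets are adapted by an evolutionary search: parents
are drawn from $K^{(n)}$ proportionally to their truncated weights,
children are single random bit flips (plus a 0.2 rate of second
flips), and the $|K|$ distinct states with the highest joint density
survive.  Elitist selection makes the truncated mass non-decreasing by
construction.  Subsets are initialized with the background-only state,
the nearest singleton states by data-to-dictionary similarity, and
random padding; the background bit is never mutated.

The M-step applies, once per iteration, the fixed-point updates

$$ W_{dh} \leftarrow
   \frac{\sum_n \langle A_{dh} \rangle_{q_n} \log y_d^{(n)}}
        {\sum_n \langle A_{dh} \rangle_{q_n}}, $$

and likewise for $V$ with $\log(1 - y)$, where $A_{dh}(s)$ indicates
that cause $h$ dominates observable $d$ under state $s$; priors update
to the mean posterior marginals.  For a *fixed* dominance structure
these updates exactly maximize the expected complete-data
log-likelihood (a property of the mean-value parameterization); they
are fixed-point rather than guaranteed-ascent steps only because the
dominance structure itself moves with the parameters.  After every
update the digamma system is re-solved elementwise to refresh
$M(\Theta)$ and $\Sigma^2(\Theta)$.

### Numerical choices

* **Digamma-system solver.**  An alternating inverse-digamma fixed
  point warm-starts a damped 2-D Newton iteration; $\psi^{-1}$ itself
  is Newton with the standard asymptotic initializer.  Residual
  tolerance is $10^{-12}$, scaled by $\max(1, |w|)$ so that the
  extremely negative mean-value parameters arising from means clamped
  near 0 remain solvable at double precision.  Symmetric inputs
  ($w_1 = w_2$) are accepted: the textbook bijectivity argument wants
  distinct shapes (a minimal exponential-family representation), but
  the numeric system is well conditioned at symmetry.
* **Clamping.**  Data at exactly 0 or 1 are shifted inward by
  $\varepsilon = 10^{-10}$ so the sufficient statistics stay finite.
* **Dominance ties** break to the lowest cause index — deterministic
  and order-stable; the background wins only where no active cause
  exceeds it.
* **Zero-responsibility columns** (an empty denominator in the
  fixed-point update) are held at their previous values, the unique
  continuous choice where the update is undefined.
* **Datapoints initialization.**  Dictionary columns are the
  $\log y$ / $\log(1-y)$ values of randomly chosen data points, priors
  start at 0.3.  Raw data-point logs satisfy
  $e^{w_1} + e^{w_2} = 1$ exactly — the zero-variance boundary of the
  mean-value domain, where the digamma system diverges — so both logs
  are shifted by `init_offset` (default 0.05), which corresponds to a
  finite concentration of roughly $1/\texttt{init\_offset}$ around the
  chosen point.  Offsets between $10^{-2}$ and $10^{-1}$ behave
  equivalently in our benchmarks; near-delta initializations
  (offset $\le 10^{-3}$) degrade optimization noticeably.
* **Variance freezing.**  With `variance_freeze_fraction` $> 0$ the
  first such fraction of iterations update only the means and priors:
  the updated $(W, V)$ are projected back to the initial variances
  (capped at 0.95 of the Beta feasibility bound
  $\mu(1-\mu)$).  This mirrors the warm-up that stabilizes the image
  experiments; the restricted scalar family freezes $\sigma^2$
  directly.
* **Scalar-variance M-step.**  No closed form is available for the
  restricted family, so each mean entry is maximized numerically on
  its feasible interval given $\sigma^2$, then $\sigma^2$ on
  $(0,\, 0.95 \min_d{}_h M_{dh}(1 - M_{dh}))$ — coordinate-wise ascent
  of the same expected complete-data log-likelihood, using the same
  responsibility sums as the full model.

## What the synthetic generators emulate

**Bars test** (`make_bars_fixture()`).  The classic non-linear
component-extraction benchmark: ten bar-shaped mean fields (value 0.9
on five pixels of a 5×5 grid) over a 0.08/0.22 checkerboard
background, per-bar prior 0.2 (two active bars per point on average),
N = 1000 points.  Standard-deviation fields are bar-like patterns with
values 0.1–0.2 arranged along each cause's own bar — the only pixels
whose variances influence the likelihood are those the cause actually
dominates — with arrangements that differ between causes; causes 1
and 5 share an identical mean bar and differ *only* in their variance
profiles (ascending vs descending), probing separation by variance
alone.  The background standard deviations form a 0.01/0.05
checkerboard.  Exact variance fields in the original benchmark are
shown only graphically, so the arrangements here are this package's
own choice within the published value ranges.

Two properties of this generator matter for interpreting results.
First, bar pixels at mean 0.9 with standard deviations 0.1–0.2 imply
J-shaped Beta distributions (second shape parameter below 1) with an
appreciable mass near the upper boundary — the benchmark is
deliberately heavy-tailed.  Second, the equal-mean pair makes ten a
hard ceiling: a run only reaches it by spending two components on the
same mean bar.  In our runs full EM from random datapoint
initializations typically recovers five to seven bars under the greedy
one-to-one matcher in `score_bar_recovery()`; runs started at the
ground truth retain all ten, so the losses are local optima of the
optimization (the equal-mean pair merging into one component with
roughly the combined prior mass, plus occasional dying components),
not a limitation of the model or updates.  The same local optima are
behind the free-energy caveat below.  (Run averages near six are what
`scripts/acceptance.R` reports; individual runs range from about three
to eight.)

**Free-energy monotonicity.**  Because the M-step is a fixed-point
step through a discontinuous argmax, the free-energy trace is not
formally guaranteed to ascend.  In well-converged basins it does; in
merged-component basins the trace can enter small persistent
oscillations (period-2 cycles of a few nats on totals of order
$5 \times 10^4$) driven by dictionary entries hovering at the
background plateau — the parameter region where the likelihood is
flat by construction.  The package reports traces as computed and
does not smooth them.

**Disease profiles** (`default_disease_profile()`,
`make_disease_fixture()`).  A two-disease audiological toy over nine
symptom descriptors on the 0 (normal) to 1 (pathological) scale: four
hearing-threshold descriptors by frequency range, two suprathreshold
descriptors, and binaural, neural and cognitive descriptors.  Cause 1
emulates high-frequency hearing loss (severe high-frequency
descriptors); cause 2 a flat *moderate* broadband loss whose graded
severities (0.3–0.55) deliberately straddle a mid-scale binarization
threshold — the regime where thresholding discards exactly the
information a continuous model retains, which is the scientific point
of modelling interval data directly.  Priors (0.45, 0.28) mirror a
clinical cohort with roughly half high-frequency and a quarter
broadband patients, co-occurrence allowed.  Real symptom data differ
from this generator in ways the tests cannot probe: correlated
symptom noise, missingness, labeling error, and profiles not drawn
from the model family itself.  Passing the simulator benchmark shows
the inference machinery separates causes it can in principle
represent; it does not certify clinical performance.

**Patches and denoising** (`make_patch_fixture()`,
`make_structured_image()`).  Desk-scale stand-ins for natural-image
experiments: oriented step edges with strongly heterogeneous
per-component noise levels (the regime where individual variance
dictionaries should beat a shared variance), and a piecewise-constant
structured image for the denoising pipeline.  They reproduce the
qualitative structure — non-linear occlusion-like superposition,
component-specific variability — but not the statistics of natural
images; free-energy comparisons on them support the relative ordering
of model families, not absolute values.

## The denoising estimator

`denoise_image()` rescales the image to \[0.2, 0.8\], corrupts it with
mean-preserving Beta noise of target standard deviation 0.3 (capped at
0.95 of the feasibility bound, which is required near the interval
ends; the original noise operator is not fully specified, so
mean-preserving corruption is this package's interpretation), extracts
overlapping patches (stride 1 by default), fits the scalar-variance
model with truncated E-steps, and estimates every pixel as the
truncated-posterior expectation of the dominant-cause mean,
$\hat y_d = \langle \bar\mu_d(s, \Theta) \rangle_{q^{(n)}}$.
Overlapping estimates are averaged; pixels left uncovered by the patch
grid (possible at stride > 1) fall back to the input.  PSNR uses peak
1 on the unit intensity scale and is capped at a 100 dB sentinel for
identical images.

## Problem sizes and defaults

The built-in experiments run at desk scale, chosen so that each
pipeline exercises the same machinery as a full-scale study on one
workstation: bars at N = 1000, D = 25, H = 10 with exact E-steps and
50 iterations across ten seeded runs; disease profiles at N = 1500
per seed with exact E-steps, eight restarts (the run with the highest
final free energy is kept — the standard guard against local optima,
and the selection rule used throughout) and a noisy-OR baseline at
binarization threshold 0.5; patch comparisons at N = 5000, D = 36,
H = 12 with truncated E-steps (40 states, 15 iterations, 30% variance
freeze); denoising on a 48-pixel structured image with 6×6 patches,
H = 12 and 24 truncated states.  The truncated machinery accepts `H`
up to 30 (states are stored as integer bitmasks); exact enumeration is
capped at `enum_cap = 15`.

The datapoints initialization is the default everywhere, including
the image-like experiments, where it converged more reliably than the
mean-plus-noise scheme in our benchmarks; `init_scheme =
"data_mean_noise"` (means from the perturbed data mean, priors and
standard deviations uniform on (0, 1) with infeasible draws rejected)
remains available and is the scheme described for large-scale image
runs in the literature this model family comes from.

## Known limitations

* Exact inference is exponential in `H`; beyond `enum_cap` only the
  truncated path applies, and its subsets are a heuristic — the free
  energy then bounds the likelihood from below without a gap
  guarantee.
* The fixed-point M-step can oscillate near dominance plateaus (see
  above); fixed iteration counts are used rather than convergence
  detection by default (`convergence_tol` is opt-in).
* Cause labels are unidentified up to permutation, and the bars
  benchmark's equal-mean pair is frequently merged from random
  initializations; evaluation utilities match labels before scoring.
* The Beta likelihood is sensitive to boundary-saturated values;
  clamping bounds the sufficient statistics at about $\pm 23$ nats,
  which truncates genuinely heavy tails of J-shaped components.
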