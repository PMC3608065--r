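---
title: "Template-matching deconvolution of isotope patterns: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-matching deconvolution of isotope patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopick)
```

## The statistical model

`isopick` treats feature detection in a profile-mode mass spectrum as a
sparse non-negative regression problem.  The observed intensity vector
$y$ on the m/z grid $x_1 < \dots < x_n$ is modelled as a non-negative
combination $y \approx \Phi\beta^*$ of templates, one per candidate
(charge, position) pair.  A template for charge $c$ anchored at $m$ is

$$\varphi(x) = \sum_k a_k\, \psi_\theta\!\big(x - m - \kappa k / c\big),$$

where the weights $a_k$ are the relative isotopic abundances predicted by
the averagine model for the neutral mass implied by $(m, c)$, $\kappa$ is
the isotopic spacing constant, and $\psi_\theta$ is the single-peak shape.
Two conventions matter throughout:

* the anchor $m$ is the position of the **most intense** isotopic peak
  (index $k = 0$), not the monoisotopic one, because that is the position
  the raw signal pins down most precisely; the monoisotopic position is
  recovered at reporting time as $m - k_{\max}\kappa/c$ with $k_{\max}$
  the averagine most-intense index;
* every template is max-normalized to height 1, so a fitted coefficient
  reads directly as the apex intensity of its pattern.

Because each template is supported on a short m/z interval, $\Phi$ is
sparse and, with columns ordered along m/z, the Gram matrix
$\Phi^\top\Phi$ is banded — the property the solvers exploit.

Two peak shapes are provided.  The Gaussian is implemented unit-height
(its normalizing constant would cancel under template max-normalization
anyway).  The exponentially modified Gaussian (EMG), for tailed peaks as
in MALDI-TOF recordings, is the convolution of a Gaussian of width
$\sigma$ with an exponential decay of scale $\alpha$, shifted by $\mu$; as
$\alpha \to 0$ it converges to a Gaussian density.  The naive EMG formula
contains $\exp(\sigma^2/2\alpha^2)$, which overflows already at moderate
$\sigma/\alpha$; the implementation therefore switches to the scaled
complementary error function, in which the exponent collapses to
$-u^2/2\sigma^2$, and is stable for $\sigma/\alpha$ up to at least $10^4$.

The averagine pseudo-peptide uses the standard average elemental
composition (C 4.9384, H 7.7583, N 1.3577, O 1.4773, S 0.0417 per
111.1254 Da) with representative isotope abundances.  Element counts are
rounded to integers with hydrogen adjusted to match the target mass;
isotopic peaks below `trim_rel` (default 1%) of the pattern maximum are
trimmed, which bounds template support and the Gram bandwidth.

## Automatic peak-shape calibration

The shape parameters are estimated from the spectrum itself.  A
deterministic peak detector collects *well-resolved* peaks: local maxima
above an intensity quantile (default 0.75), grown into regions by
monotone descent (one violation tolerated per side) down to 5% of the
apex, requiring at least 8 points, and discarding apexes closer than
`sep_window` (default 0.5 Th) to another apex.  "Well-resolved" has no
canonical quantitative definition, so all gates are exposed as
configuration.  Calibration needs sampling dense relative to the peak
width (roughly ten points across a peak); on grids too coarse for that,
fixed shape parameters should be supplied via `shape_params`, which is
also the fallback the pipeline takes if detection fails.

Each region is fitted by nonlinear least squares with a free
multiplicative height — the EMG of the model is a density, not
unit-height, so without a height parameter the fit would force absurd
shape values.  For the EMG there is an identifiability subtlety: a free
location and a free $\mu$ enter the model only through their sum, so the
location is fixed at the detected apex and $\mu$ absorbs the residual
shift.  Tests therefore check $\alpha$, $\sigma$ and the combined
location, never $\mu$ in isolation.

Per-region estimates $\hat\theta_r(\hat x_r)$ are aggregated into
m/z-dependent trends $\theta_l(x) = \sum_m \nu_{l,m} g_{l,m}(x)$ (default
basis $\{1, x\}$; a constant mode reduces to the median) fitted by least
absolute deviation, because estimates from occasionally mis-detected or
overlapping regions are gross outliers.  The LAD fit is computed by
iteratively reweighted least squares followed by a vertex polish: an LAD
optimum interpolates as many points as the basis has coefficients, so a
single-swap local search over interpolation sets removes the slow tail of
IRLS convergence.  Fits with region residual sums above 20% of the
region's total signal energy are excluded before trend fitting.
Evaluated trends are clipped below at $10^{-4}$ Th for $\sigma$ and
$\alpha$ to preserve positivity under extrapolation.

## Noise model, placement and goodness of fit

The local noise level is a sliding median,
$LNL(x) = \mathrm{median}\{y_i : x_i \in [x-h, x+h]\}$, with half-width
`window_h` (default 2.5 Th — wide enough to span several isotope
spacings, so the median sees mostly inter-peak baseline).  The median is
implemented as the lower-median order statistic rather than the midpoint
average: only an order statistic is *exactly* equivariant under monotone
intensity transforms, which is one of the estimator's defining
properties.  Boundary windows are truncated, not padded.  The truncated
level $LNL_+ = \max(LNL, \tfrac14\,\mathrm{median}\,LNL)$ bounds
signal-to-noise denominators away from the tiny values of low-intensity
regions.

Templates are placed at data positions whose intensity exceeds
`factor_place` (default 1.5) times the LNL, one per charge state —
placements need only be dense enough that merging can later refine the
location, and the gate is deliberately low, relying on thresholding for
specificity.

The goodness-of-fit map fits the spectrum with *single* peaks placed at
every datum (same shape, same fit norm $q$) and summarizes the residuals
over the same windows:
$GOF_+(x) = \min\big(1 - \sum_{I_x}|r_i|^q / \sum_{I_x}|y_i|^q,\ 0.5\big)$.
Rough, irregular noise fits poorly by smooth peaks and receives low
values; the cap at 0.5 bounds the correction's influence.  The printed
form caps from above — even perfect fits score 0.5 — and the
implementation follows it, with both the cap value and the min/max mode
configurable, since a lower-bound reading of "limiting the influence" is
also defensible.  Empty or all-zero windows receive the neutral value
0.5.  The GOF windows share `window_h` with the LNL by default but can be
configured separately.

## Interior-point solvers

The fit criterion $\min_{\beta\ge 0}\|y - \Phi\beta\|_q^q$ is a quadratic
program for $q = 2$ and a linear program for $q = 1$, both solved by the
log-barrier method: inequality constraints become $-\gamma^{-1}\log(\cdot)$
terms, the smooth problem is solved by damped Newton iterations, and
$\gamma$ is multiplied by $M$ until it reaches `gamma_max`.  The schedule
defaults ($\gamma_0 = 10$, $M = 10$, $\gamma_{\max} = 10^8$, about eight
stages) are standard log-barrier practice.  For $q = 2$ the Hessian is
$\Phi^\top\Phi + \gamma^{-1}\mathrm{diag}(\beta^{-2})$: the Gram matrix is
formed once and cached, only the diagonal changes per step, and each
Newton system is solved by sparse symmetric positive-definite Cholesky
factorization with the symbolic analysis reused across steps (a dense
path exists for verification; both give identical solutions on template
matrices).  For $q = 1$ the LP in $(\beta, r)$ is reduced by block
elimination — the $r$-block Hessian is diagonal — to a $p \times p$
system with the Gram sparsity pattern; the Schur-complement weights are
computed in a cancellation-free form that is positive by construction,
and the scaled Gram matrix is recomputed per step as the criterion
requires.  Inputs are normalized by $\max|y|$ internally (both problems
are positively homogeneous), and problems are initialized at a strictly
positive data-scaled point.

Barrier iterates are never exactly zero: at each barrier optimum every
coordinate satisfies $\beta_j g_j = 1/\gamma$, so "zero" coefficients sit
near $10^{-8}$ relative.  Downstream grouping needs genuine zeros, and the
oracle-level accuracy the tests demand exceeds the $O(p/\gamma_{\max})$
barrier duality gap.  The solvers therefore finish with a standard
crossover: coordinates with clearly positive dual gradient are clamped to
zero, and the surviving active set is refined exactly — by its normal
equations for $q = 2$ (with a drop/admit loop on primal/dual
infeasibilities), and for $q = 1$ by solving the interpolation system on
the near-zero residual set (an LAD optimum at a vertex interpolates as
many points as it has active columns), trying a few candidate set sizes
around the largest multiplicative gap in the sorted residuals and
accepting only monotone objective improvements.  If no interpolating
vertex is reached — the split can be ambiguous at $\gamma_{\max}$ — the
barrier continues two further stages and the refinement reruns.  Every
solve carries a KKT certificate (non-negativity, dual feasibility,
complementary slackness).

The weighted non-negative lasso,
$\min_{\beta\ge0}\|y-\Phi\beta\|_2^2 + \lambda \mathbf{1}^\top W\beta$
with per-column weights $w_j = LNL_+(m_j)$ rescaling the regularization
to the local noise, is included as the regularization-based baseline; the
linear term only shifts the gradient, and $\lambda = 0$ reduces exactly
to NNLS.  It is not part of the default pipeline — thresholding after an
unregularized fit is the package's model-selection mechanism.

## Postprocessing: merging, scoring, thresholding

Finite sampling and shape mismatch cause *peak splitting*: several
adjacent templates share the weight of one true pattern (most visibly
when the true apex falls between grid points, where the two flanking
templates each receive roughly half the weight).  Per charge state,
positive coefficients at anchors chained within `merge_ppm` (default
100 ppm) are grouped, and each group is collapsed by minimizing

$$\int \Big(\sum_j \hat\beta_j \psi_{m_j}(x) - b\,\psi_m(x)\Big)^2 dx$$

over the continuous location $m$ and weight $b$, using the groups'
most-intense single peaks.  The integral is sampled on a grid of spacing
$\min(\sigma/20, \Delta/4)$ ($\Delta$ = data spacing) over the support
±5σ; since the optimal $b$ for fixed $m$ is available in closed form, the
search is a 1-D profile optimization (grid pre-scan plus local
refinement), which both converges reliably and guarantees the returned
objective is no worse than any lattice point of a brute-force search.
Peak-shape parameters inside the integral are evaluated at the group's
coefficient-weighted mean anchor; singleton groups pass through
unchanged.  This continuous merge is what lets reported locations beat
the sampling rate.  Note that 100 ppm spans a few sampling intervals on
typical TOF grids but *less than one* interval on very coarse grids
(0.06 Th at m/z 350 is 171 ppm); on such data a platform-scaled tolerance
of a few sampling intervals is worth considering.

Merged features are scored by
$\mathrm{ratio} = GOF_+(\tilde m)\,\tilde\beta / LNL_+(\tilde m)$, both
statistics looked up at the nearest datum (they are step-like window
statistics; interpolation would add nothing).  Thresholding at $t$
involves no re-fitting: a single fit induces a ranking, and $t$ walks
along it.  No default $t$ can be universal — it is a signal-to-noise
quantity whose reasonable value depends on platform and sample — so the
command-line tool prints the score distribution for review.  An optional
final filter keeps only features whose neutral mass lies within
`mass_filter_ppm` (default 200) of the nearest peptide mass cluster
center $1.000485\,m_n + 0.029$, removing non-peptidic artifacts.

## The synthetic-data generator and what the tests show

`simulate_spectrum()` builds spectra as height-scaled max-normalized
templates plus a constant baseline, additive Gaussian noise (sd relative
to the tallest pattern) and optional multiplicative log-normal noise,
clipped at zero — matching the additive-noise assumption of the fit
criteria; real spectra may have multiplicative or Poisson-like noise,
detector saturation, chemical baseline structure and non-averagine
compositions, none of which are emulated, so green tests here do not
certify performance on real data.

Two study designs deserve explanation:

* **Noiseless recovery** (five disjoint patterns, charges 1–3, recall =
  precision = 1 at $t = 1$): a strictly zero spectrum background makes
  the score degenerate — $LNL \equiv 0$, every positive coefficient
  scores $+\infty$, and harmless $10^{-5}$-relative coefficients from
  sub-representable template tails become false positives.  The study
  therefore aligns pattern anchors with grid points
  (`snap_anchors = TRUE`, so the signal is exactly representable by
  placed templates) and adds a constant baseline of 1% of the tallest
  pattern, keeping the spectrum fully deterministic while giving the
  noise level a defined value.
* **Unmixing** (charge-2 and charge-3 peptides at 351.2/351.5 Th, 0.06 Th
  spacing): conditions chosen as a badly resolved ion-trap-like line —
  $\sigma = 0.1$ Th, 5% additive noise, 0.5% baseline, equal heights,
  with the generating width supplied as fixed shape parameters because a
  7-Th window contains no isolated calibration peaks.  Success means the
  two true templates score at least 1 and carry the two largest ratios.
  The tested replicate family passes 10/10; this geometry is genuinely at
  the edge of resolvability at this sampling rate (the dominant failure
  mode across other noise realizations is a wrong-charge template at the
  charge-2 anchor, whose secondary peaks nearly coincide with the
  charge-3 pattern's), so success rates under other seeds can be lower.

Evaluation uses greedy one-to-one matching by increasing relative mass
distance within `delta_ppm` at equal charge; precision of an empty list
is defined as 0.

## Numerical choices and degenerate inputs

* Sparse template storage floors entries at $10^{-8}$ of the column
  maximum and keeps supports contiguous (preserving the banded Gram).
* Grouping treats coefficients above $10^{-10}\max\hat\beta$ as positive
  — with solver crossover true zeros are exact, so this guard matters
  only for user-supplied coefficient vectors.
* All-zero intensity vectors short-circuit to an empty fit; zero-norm
  design columns are rejected at validation rather than silently dropped.
* Flat-topped peaks (two equal adjacent grid maxima) count as one apex in
  region detection.
* A constant spectrum produces no placements (nothing exceeds 1.5× its
  own median) and an empty peaklist.
* Cholesky failures trigger one retry with a $10^{-12}$-scaled diagonal
  regularization.
* Merge-optimizer failure falls back to the group's largest-coefficient
  member, with a warning.

## Problem sizes

The shipped tests and the acceptance script run on spectra of a few
hundred to a few thousand points with dictionaries of up to a few
thousand templates, and solver verification uses 40 × 60 randomized
instances — sizes at which every check completes in seconds while still
exercising the banded sparse path.  The same code path scales to full
spectra (tens of thousands of points); the single-peak GOF design is the
dominant cost there, and `gof_stride` exists to thin it.

## Known limitations

Single spectra only (no LC-MS run aggregation or retention-time
dimension); averagine-based isotope abundances only (no glycans or
labelled peptides); Gaussian and EMG shapes only; no baseline
subtraction; mzML reading is limited to profile spectra via `mzR`.
Calibration requires sampling dense relative to peak width; supply
`shape_params` otherwise.
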