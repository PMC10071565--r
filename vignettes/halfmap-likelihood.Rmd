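---
title: "Half-map error models and likelihood targets for docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-map error models and likelihood targets for docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodock)
```

## The problem

Placing an atomic model into a single-particle cryo-EM reconstruction is
the cryo-EM analogue of molecular replacement. Unlike crystallography, the
reconstruction retains phases, which makes the translation problem easy
once an orientation is known — but it also means the reliability of every
Fourier term must be quantified before a likelihood score can be trusted.
In cryo-EM that reliability varies strongly with both resolution and
*direction*: preferred particle orientations leave direction-dependent
noise, and overall anisotropic displacements of the imaged object leave
direction-dependent signal.

`cryodock` estimates the signal power $\Sigma_S$ and noise power
$\Sigma_E$ of every Fourier term from a pair of unfiltered, unmasked
half-maps, converts them into a per-term quality $D_\mathrm{obs}$, and
uses that quality to build likelihood targets for orientation search,
translation search and rigid-body refinement of a docked model, plus the
expected scores (eLLG) and information-gain measures used to plan a
docking strategy.

## The error model

Matching Fourier terms of the two half-maps are modelled as

$$\mathbf{F}_1 = A\mathbf{T} + \boldsymbol{\varepsilon}_1,\qquad
  \mathbf{F}_2 = A\mathbf{T} + \boldsymbol{\varepsilon}_2,$$

with $\mathbf{T}$ the transform of the atoms at rest (complex normal with
variance $\Sigma_T$), $A$ a resolution- and direction-dependent damping
factor, and independent complex-normal noise of variance $\Sigma_E$. The
joint density of $(\mathbf{F}_1, \mathbf{F}_2)$ is a bivariate complex
normal with diagonal $\Sigma_S + \Sigma_E$ and off-diagonal
$\Sigma_S = A^2\Sigma_T$ (`bivariate_loglik()`).

Maximising the summed log density over a small sphere of terms in index
space has an analytic solution:
$\hat\Sigma_S = \langle\mathrm{Re}\,\mathbf{F}_1\mathbf{F}_2^*\rangle$
(an unnormalised half-map correlation) and
$\hat\Sigma_E = \tfrac12\langle|\mathbf{F}_1-\mathbf{F}_2|^2\rangle$.
`local_variance_field()` evaluates these for every term at once by FFT
convolution with a spherical kernel (default about 100 terms per
neighbourhood). The local estimates make no assumption about the shape of
either field — essential for $\Sigma_E$, whose preferred-orientation
modes need not obey any symmetry — but the signal estimate becomes noisy
wherever signal is weak.

For the signal, a smooth parametric alternative is refined
(`refine_signal_model()`):

$$\Sigma_S(\mathbf{h}) = A_0^2\,
   e^{-\mathbf{h}^{*\top}\beta_A\mathbf{h}^{*}/2}\;
   m_{\mathrm{bin}(s)}\,B(s),$$

where $\beta_A$ is a symmetric anisotropic tensor (Å$^2$), $B(s)$ is a
reference spectral power curve, and the binwise multipliers $m$ are
restrained to one on the log scale, more weakly at low resolution where
true spectra vary most between structures. The reference curve shipped
with the package is a synthetic smooth stand-in with the characteristic
macromolecular features (shape spike at low $s$, secondary-structure
feature near 10 Å, favoured-distance peak near 4.5 Å); any user-supplied
two-column table can replace it (`best_curve()`). Because the restraint is
weak, the curve mainly stabilises the weak-data regime.

The two estimates are blended per term by a logistic sigmoid of the local
Fourier sphere correlation (`hybrid_sigma_s()`; steepness 9, midpoint
$0.95$), so the assumption-free local estimate wins where the half-maps
agree well and the smooth model wins where they do not. The hybrid, floored
at zero, gives the per-term quality

$$D_\mathrm{obs} = \sqrt{\frac{\Sigma_S}{\Sigma_S + \Sigma_E/2}},$$

the single-term analogue of $\mathrm{FSC}_\mathrm{ref}$, and normalised
coefficients $E_\mathrm{mean} = F_\mathrm{mean}/\sqrt{\Sigma_S+\Sigma_E/2}$.

### Numerical choices

* **Resolution bins.** Equal-count bins; the default is 40. With 20 bins
  the transition region between signal-dominated and noise-dominated
  resolution was visibly under-resolved on the reference synthetic fixture
  (the fitted signal model fell about two-fold short in the transition
  shells); 40 bins with the same restraint scheme track it with no
  stability cost. A second-difference smoothness penalty across bins is
  available (`smooth_weight`) but off by default: with a reference curve
  that does not match the data's spectrum exactly, the multipliers need
  genuine curvature to correct its shape.
* **Restraints.** Quadratic penalty on $\log m$ with weight rising by a
  factor of 4 from the lowest- to the highest-resolution bin
  (`restraint_base`, default 1).
* **Floors and caps.** $\Sigma_E$ is floored at $10^{-10}$ of the mean
  term power; $D_\mathrm{obs}$ is capped at $1-10^{-9}$ before logarithms.
  Negative raw local $\Sigma_S$ values are kept for correlation purposes
  and floored at zero only where non-negativity matters.
* **Optimisation.** L-BFGS-B with analytic gradients for the signal
  model; parameter scaling keeps the tensor and multiplier blocks
  comparable. The objective is guarded against overflow so that wild
  trial steps fail gracefully inside the line search.

## Likelihood targets

With model coefficients $E_C$ (Gaussian-atom synthesis of the posed model,
transformed and normalised; translations applied exactly as Fourier phase
shifts) and the model quality

$$\sigma_A(s) = \sqrt{f}\, e^{-2\pi^2\Delta^2 s^2/3}$$

($f$ completeness, $\Delta$ the r.m.s. radial coordinate error of a 3D
Gaussian error model — the exponent is the characteristic function of that
Gaussian), each term contributes, with $x = D_\mathrm{obs}\sigma_A$,

$$\mathrm{LLG} = -\log(1-x^2)
  - \frac{x^2(E_\mathrm{mean}^2+E_C^2)}{1-x^2}
  + \frac{2xE_\mathrm{mean}E_C\cos\Delta\phi}{1-x^2}.$$

This is exactly the log ratio of the conditional complex-normal density of
$E_\mathrm{mean}$ given $E_C$ to the uninformative ($\sigma_A=0$) density;
it vanishes identically for an uninformative model. Only the
$\cos\Delta\phi$ term changes under translation, so the LLG over the full
grid of translations is computed exactly with one FFT
(`translation_search_fft()`); the implementation verifies on every call
that the correlation + scale + offset decomposition matches the direct
sum. Orientations are scored with the amplitude-only Rice-likelihood
analogue (`rotation_score()`), evaluated directly on a quasi-uniform
orientation grid — correctness over speed at desk scale.

Rigid-body refinement (`refine_pose()`) maximises the total LLG over three
perturbation rotations about the model's centre of mass, three
translations, $\Delta$, and a cell scale factor that absorbs voxel-size
error; rotations about the centre of mass keep the rotation and
translation blocks of the Hessian nearly orthogonal. $\Delta$ is bounded
to $[0.1, 3]$ Å (initialised at 1 Å, the typical refined range being about
0.8–1.2 Å) and the cell scale to $[0.9, 1.1]$.

Totals are multiplied by the oversampling factor — the ratio of the
particle volume to the box volume — because the transform of a padded
reconstruction is oversampled and neighbouring terms are correlated. The
same factor corrects all expected scores and information sums.

### A note on negative LLG values

The LLG is a likelihood *ratio* score. If $\sigma_A$ claims more
correlation than the data deliver — for instance a fixed small $\Delta$,
or a strongly anisotropic blur that the isotropic $\Delta$ model cannot
represent — the total LLG at the true pose can be strongly negative.
Refining $\Delta$ is the intended mechanism and restores a positive,
meaningful score. Likewise a model unrelated to the map scores *below*
zero (around minus the total expected LLG), not at zero: a wrong model is
worse than no model.

### Model normalisation and the cell scale

Two normalisation details matter far more than they appear to.

First, the normalisers must be smooth functions of resolution: a
piecewise-interpolated shell normaliser leaves a bin-scale sawtooth in the
model envelope that moves when the cell scale changes and can lock onto
structure in the data envelope, biasing the refined scale by several
tenths of a percent. All normalisers are therefore low-df smoothing
splines of shell log-powers in log-$s$ coordinates.

Second, the data and model coefficients must share one normalisation
convention per term. $E_\mathrm{mean}$ is normalised by
$\sqrt{\Sigma_S + \Sigma_E/2}$, and the hybrid $\Sigma_S$ tracks the
*realised* local spectrum of the imaged structure — it is a speckled
field, not a smooth curve. If the model is normalised by a smooth curve
instead, the per-term ratio of the two conventions carries that speckle;
at strong terms (where $1/(1-D_\mathrm{obs}^2\sigma_A^2)$ reaches
$10^3$–$10^4$) even a few-percent per-term mismatch overwhelms the score,
inflates the refined $\Delta$, and drags the cell scale through their
coupling. Prepared data therefore carry their effective per-term
denominator, and `model_to_efc()` divides the model transform by the very
same field before its smooth unit rescale. With this convention a perfect
model refines to a small $\Delta$, reaches about 90% of the
information-gain bound, and the cell scale is recovered to a couple of
parts per thousand.

## Expected scores and information gain

Before any search, the per-term expected scores are available in closed or
semi-closed form with $x = D_\mathrm{obs}\sigma_A$:

* translation: $\mathrm{eLLG}_\mathrm{tra} = -\log(1-x^2)$, the mutual
  information between two $x$-correlated complex coefficients;
* rotation: the mutual information between their *amplitudes* —
  $x^4/2 - \tfrac23 x^6$ for small $x$ (series), Gauss–Legendre quadrature
  in the mid range, a ridge-adapted quadrature (Rayleigh $\times$ Rice
  factorisation) as $x \to 1$, and the exact asymptotic slope
  $-\tfrac12\log(1-x^2)$ beyond $x = 1-10^{-6}$ where double precision
  cancels. Because amplitudes discard phases, the rotation score never
  exceeds the translation score; at $x=0.01$ the ratio is about 20 000,
  and the two scale oppositely with subvolume size (rotation total
  inversely proportional to volume, translation total nearly independent
  of it in the weak regime).

The information gained about a Fourier term by the reconstruction is the
Kullback–Leibler divergence from prior to posterior of the true
coefficient, which equals the eLLG of a perfect model:
$D_{KL} = -\log(1-D_\mathrm{obs}^2)$ nats. Summed per shell with the
effective independent-term count $K$ (raw count times the oversampling
factor), and mapped through the half-map relation
$D_\mathrm{obs}^2 = 2\,\mathrm{FSC}/(1+\mathrm{FSC})$, this reproduces the
Fourier-shell-information form $K\log_2[(1+\mathrm{FSC})/(1-\mathrm{FSC})]$
exactly; the per-term form is more general because anisotropy spreads
$D_\mathrm{obs}$ within a shell. Terms carrying less than 0.01 bit
(after the oversampling correction by default; a flag exposes the
alternative) are dropped before docking searches.

## The synthetic generator

`synthetic_spec()` defines a fully known study condition: a coil-like
random-walk chain of Gaussian atoms (default 300 atoms, width 1.5 Å) in a
20 Å-radius cluster centred in a $64^3$ box at 1.2 Å voxels; a true
anisotropic damping tensor applied in Fourier space (default
$\mathrm{diag}(30, 60, 110)$ Å$^2$); and a smooth directional noise field
emulating preferred orientations (a single mode along $z$ by default, not
constrained to ellipsoidal form), with the overall noise level set so that
the mean $D_\mathrm{obs}$ crosses 0.5 near half the Nyquist frequency —
one fixture that spans the strong-, mixed- and weak-signal regimes. Two
independent noise draws coloured in Fourier space give the half-maps;
bit-identical outputs follow from one seed.

What the generator does *not* emulate: CTF effects, per-particle motion,
radiation damage, masking artefacts, solvent structure, or coupling
between conformational variation and orientation preference. Passing the
recovery tests therefore shows that the estimators are correct under the
model's own assumptions, not that real reconstructions obey those
assumptions.

Ground truth records the blurred true transform, per-term
$\Sigma_S, \Sigma_E, D_\mathrm{obs}$ (the true $\Sigma_T$ is bookkept as a
60-narrow-shell mean of the unblurred spectrum, fine enough to resolve the
molecular-shape spike at low $s$), and the atom coordinates.

Validation problem sizes were chosen to keep the full suite comfortable on
one CPU: the $64^3$/300-atom fixture for estimator recovery, and a
$48^3$/200-atom signal-dominated fixture (milder tensor
$\mathrm{diag}(20,30,40)$, reduced noise) for docking recovery — milder
because pose and cell-scale recovery are best measured where the isotropic
model-error family nearly contains the truth; robustness to strong
anisotropy is exercised separately by the error-model tests.

## Design decisions taken where the design was open

* Sphere extraction uses a 3-voxel cosine taper (soft edges keep the
  subvolume spectrum clean while preserving the property that masking
  effects vary between subvolumes).
* The hybrid sigmoid midpoint is $k_0\cdot c^\ast$ with $c^\ast$ fixed at
  1 rather than the data-set maximum correlation, so the blend is a total,
  data-independent function; at a local correlation of 1 the tensor model
  still receives weight $\approx 0.39$.
* $\mathrm{CC}_\mathrm{sphere}$ uses the real part of the complex
  correlation (noise-robust and sign-preserving).
* The overall scale and the binwise multipliers are kept from trading off
  by the restraint that pulls mean log-multipliers toward zero.
* Anisotropic voxel sizes are rejected rather than resampled; resampling
  would silently change the error model.
* Orientation grids are deterministic (Fibonacci axes $\times$ uniform
  angle ladder), and equal scores tie-break by grid order.

## Known limitations

* $\sigma_A$ is isotropic in direction; strongly anisotropic blur is
  absorbed into an effective $\Delta$ (and slightly biases the refined
  cell scale, see above) rather than being modelled.
* The per-term $D_\mathrm{obs}$ from smoothed local fields cannot be
  accurate enough near $D_\mathrm{obs} \to 1$ for bound-chasing
  comparisons; information totals there should be read as indicative.
* Bulk solvent is not modelled; completeness enters as a single effective
  fraction.
* The rotation target is evaluated by direct scoring on an orientation
  grid; no FFT acceleration of the orientation search is provided.
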