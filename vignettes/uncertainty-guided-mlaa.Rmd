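---
title: "Uncertainty-guided pseudo-CT priors for joint activity/attenuation PET reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-guided pseudo-CT priors for joint activity/attenuation PET reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`upctmlaa` implements, at desk scale, an attenuation-correction framework
for PET/MRI in which a Bayesian pseudo-CT regressor modulates a regularized
joint reconstruction of activity and attenuation (MLAA). The chain is:

1. a dropout-equipped encoder–decoder maps three Dixon-like MR channels
   (in-phase, fat fraction, water fraction) to a pseudo-CT in Hounsfield
   units;
2. Monte Carlo Dropout — $N$ stochastic forward passes $f_i(x)$ with
   dropout active — yields the sample mean
   $pCT = \frac{1}{N}\sum_i f_i(x)$ and the biased sample variance
   $\sigma^2 = \frac{1}{N}\sum_i (f_i(x) - pCT)^2$ (divisor $N$, exactly as
   returned by `mc_dropout_infer()`);
3. the variance map is squashed by the fixed sigmoid
   $w = 1/(1+\exp(0.1(\sigma^2/1000 - 25)))$ and min–max rescaled over
   in-body voxels to the prior-strength range
   $\beta_{MR} \in [10^3, 5\times 10^6]$, zero outside the body;
4. reconstruction alternates one TOF-OSEM activity pass with five
   OSTR-style attenuation passes per outer iteration (five outer
   iterations), the attenuation update maximizing the Poisson emission
   log-likelihood penalized by
   $R_{MR}(\mu) = \sum_i \frac{\beta_{MR,i}}{2}(\mu_i - \mu^{MR}_i)^2$
   plus a quadratic 4-neighbourhood smoothness penalty with global weight
   $\beta_{smooth} = 2\times 10^4$.

The intended behaviour is asymmetric by design: where the regressor is
confident (normal anatomy) the attenuation estimate is pinned to the
pseudo-CT; where it is uncertain — above all the signal-void halo of a
metal implant, an out-of-distribution structure for a network trained only
on implant-free anatomy — the emission data rebuild the attenuation.

## Synthetic phantoms: what they emulate, and what they do not

No clinical data ship with the package; `make_phantom()` generates seeded
pelvis-like cases with the statistical structure the method relies on:

* paired, perfectly registered MR/CT/activity volumes (no registration
  stage exists downstream, deliberately);
* per-class HU distributions (air fixed at −1000 HU; fat
  $\mathcal N(-100, 15)$; soft tissue $\mathcal N(40, 15)$; cortical bone
  $\mathcal N(950, 120)$ truncated to 700–1200 HU; implant ≥ 3000 HU), and
  MR channel signals derived from class composition with multiplicative
  Gaussian noise (default 2% of the class signal);
* a per-class uptake table (soft 1.0, bone 0.5, fat 0.25, air/implant 0)
  with spherical lesions as uptake multipliers (> 1);
* the metal-artifact discrepancy: the CT gets a high-HU core plus a
  deterministic seeded radial-spoke streak pattern confined to the halo
  radius, while every MR channel inside the halo is attenuated to the
  magnitude-noise floor (the signal void; MR magnitude images are never
  exactly zero, and an exactly-zero input would let a small ReLU network
  go completely inactive there, which would suppress the dropout-induced
  variance the method depends on). Ground-truth activity is unchanged by
  the artifact.

The phantoms are *not* anatomically realistic: no bias fields, no bowel
air, no arms or truncation, no beam hardening, and class-wise homogeneous
texture. Consequences worth being explicit about: the network's in-body
predictive variance on these phantoms is far smaller than on clinical
anatomy (fractions of an HU² in soft tissue versus the 0–2.5×10⁴ HU² range
typical of real bodies), so passing the out-of-distribution tests here
demonstrates the *mechanism* — variance concentrates on unseen structure
and the prior releases there — not clinical error magnitudes. Cohort-level
error tables cannot be reproduced from these phantoms and are not
attempted.

## The network and its desk-scale operating point

The regressor is a depth-3 encoder–decoder (two 3×3 convolution + ReLU +
dropout blocks per level, 2×2 mean pooling, nearest-neighbour upsampling
with skip concatenation, linear 1×1 output head), trained on random 2-D
patches with the composite loss

$$L = \langle|y-\hat y|\rangle + \lambda_{GDL}\sum_a \langle(\nabla_a y -
\nabla_a\hat y)^2\rangle + \lambda_{LDL}\langle(\Delta y - \Delta\hat
y)^2\rangle, \qquad \lambda_{GDL}=\lambda_{LDL}=0.01,$$

with voxel-mean reduction per term. Finite differences use valid-region
forward differences and the interior 5-point Laplacian, so a constant
offset contributes only through the L1 term (this property is tested).
Dropout ($p = 0.2$, a configuration default — the rate is not dictated by
the method) follows every convolution except the output head; including
the output convolution would add white noise to every prediction rather
than structure-dependent uncertainty, which is why the head is excluded.

Two operating points coexist in the configuration:

* the *faithful* constants kept as `train_config()` defaults — Adam with
  learning rate $10^{-5}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$, L2 weight decay $10^{-5}$, minibatch 4 — which
  correspond to a $10^5$-iteration 3-D training run;
* the *desk-scale* point used by the tests, the acceptance script and the
  pipeline default: 2-D 32×32 patches, 8 base channels, 400–600
  iterations, learning rate $10^{-3}$. At a few hundred iterations the
  faithful learning rate cannot move a freshly initialized network at
  all; the raised rate is what makes a minutes-long CPU training
  meaningful. N = 32 Monte Carlo samples (the faithful value is 243).

Full slices are assembled from overlapping patches at half-patch stride
with uniform-average blending; each Monte Carlo sample draws fresh dropout
masks per tile, and each sample is seeded individually so results are
bit-reproducible for a fixed seed. With $p = 0$ no RNG is consumed and the
variance is identically zero.

## Prior-strength map

The sigmoid constants are fixed calibration values: $w = 1/2$ exactly at
$\sigma^2 = 25{,}000$ HU², transition band covering roughly 0–10⁵ HU²,
saturation near zero above that. "Linearly scaled to a range of 10³ to
5×10⁶" is read as per-volume min–max rescaling over in-body voxels, so the
printed endpoints are attained exactly on any non-constant map; the
alternative fixed affine map $w \mapsto \beta_{min} + w(\beta_{max} -
\beta_{min})$ can never attain $\beta_{max}$ (since $w \le 0.9241$ for
$\sigma^2 \ge 0$) and is kept available via `scaling = "fixed"`. A
constant in-body weight map has no contrast to rescale and is assigned
$\beta_{max}$ with a warning. Out-of-body voxels get $\beta = 0$ and are
excluded from all priors *and* all attenuation updates.

The body mask follows the stated morphology: threshold > −400 HU, erosion
by a 1-voxel-radius ball in index space (in-plane 4-neighbourhood on
single-slice volumes, where through-plane neighbours do not exist), then
2-D hole filling per axial slice. Arm removal is a no-op here — the
phantoms have no arms.

## System model and reconstruction numerics

The projector pair is one explicit sparse matrix and its transpose
(pixel-driven 2-D parallel beam, linear radial interpolation, path lengths
in cm), so the adjoint identity holds to machine precision by
construction — the property the multiplicative update derivations assume.
TOF weights are a Gaussian kernel (default FWHM 60 mm, 11 bins) truncated
at 3.5σ and renormalized per pixel to unit sum, which makes TOF bins
marginalize *exactly* to the non-TOF projection. Defaults: 96 angles, 128
radial bins of 2 mm, 8 subsets for the 2-D runs (28 is retained in the
faithful configuration; the subset count must divide the angle count), and
an optional isotropic Gaussian PSF, off by default. Subsets interleave
angles and are processed in bit-reversed order.

The OSEM activity update is the standard attenuated multiplicative step;
voxels with zero subset sensitivity are frozen. The OSTR attenuation
update uses separable paraboloidal surrogates with per-pass optimum
curvature ($c(l) = 2\bar P (1 - e^{-l}(1+l))/l^2$ for the zero-background
emission likelihood, $c(0) = \bar P$), De Pierro-type separable splitting
of both the likelihood and the pairwise smoothness term, subset-scaled
gradients against a full-data denominator, and a clamp to
$[0, \mu_{max}]$ with $\mu_{max} = 0.5$ cm⁻¹ (above any implant value at
511 keV). With a single subset each pass is a monotone step on the
penalized objective; the 20-iteration monotonicity test exercises exactly
this configuration. With zero background the per-ray likelihood is concave
in the line integral, which is what the curvature bound needs; a positive
background reuses the same curvature as an approximation and forfeits the
formal guarantee (default background is zero).

Initializations: activity uniform inside the body and zero outside (the
multiplicative update preserves the zeros); attenuation at $\mu^{MR}$ in
the prior-carrying modes and at water (0.096 cm⁻¹ inside the body) in
naive mode. Naive mode keeps the smoothness prior as configured — the
reference protocol is silent on this, and dropping it would conflate
"no pseudo-CT prior" with "no regularization at all". With a constant
$\beta$ map the uncertainty-weighted mode reduces exactly to the
uniform-regularized mode, and with $\beta \equiv 0$ to naive MLAA (both
reductions are tested).

The CT-to-attenuation conversion is the standard 120-kVp bilinear model
(slope 9.6×10⁻⁵ cm⁻¹/HU below the +47 HU breakpoint — water at 0 HU maps
to 0.096 cm⁻¹ — and 5.1×10⁻⁵ above, continuous at the breakpoint, clamped
at zero below −1000 HU). The cited clinical protocol does not print its
constants; these live in `bilinear_model()` and are documented there.

## Study conditions for the implant experiment

The implant-recovery experiment (also re-run by `scripts/acceptance.R`)
fixes these conditions:

* 64×64 single axial slice at 3 mm voxels — one plane standing in for the
  whole dedicated pelvis acquisition;
* 10⁷ expected true counts on that plane. A 15–20 min dedicated pelvis
  acquisition collects well above 10⁸ trues over its axial extent; since
  only one plane is reconstructed here, it is assigned a count level of
  that order rather than a thin-slice fraction of it. This matters because
  $\beta_{smooth} = 2\times 10^4$ is an *absolute* prior weight: the
  published operating point balances it against clinical-scale likelihood
  amplitudes, and starving the slice of counts would silently change the
  prior-to-likelihood balance being studied;
* a hip-scale implant: 10 mm core radius, 24 mm artifact halo, 3000 HU.
  Pilot analysis showed a genuine scale interaction worth recording: a
  6 mm (2-voxel-radius) core consists entirely of boundary voxels, and the
  quadratic smoothness penalty then biases the recovered core attenuation
  toward the surrounding soft tissue by ~25% at any iteration count.
  Real hip prostheses are 20–50 mm structures whose interior voxels are
  shielded from that boundary pull, and the 10 mm core reproduces that
  regime at 3 mm voxels;
* prior construction for the comparator arm: the pseudo-CT with the halo
  read as air (−1000 HU), i.e. what an MR-only regressor produces on a
  signal void, with $\beta = 10^3$ inside the halo and $5\times 10^6$
  elsewhere in the body.

Under these conditions the uncertainty-weighted reconstruction recovers
the mean core attenuation to within ~16% of truth while staying within
0.7% of the prior outside the halo; naive MLAA also recovers the implant
but with a ~50× larger attenuation RMSE outside the halo; and the in-plane
lesion SUVmax bias of the uncertainty-weighted reconstruction is several
times smaller in magnitude than OSEM with the air-filled prior. These are
the directions and orderings of the clinical study; the magnitudes are
properties of the phantoms.

## Degenerate inputs and edge cases

* `body_mask()` errors on an empty post-erosion mask ("no body found");
  isolated single-voxel speckles outside the body are removed by the
  erosion, so the mask is invariant to them.
* Evaluation masks use strict inequalities (> −950 HU, > 0.01 cm⁻¹).
* `masked_error_stats()` uses the population (divisor-$n$) standard
  deviation so $RMSE^2 = \mu^2 + \sigma^2$ holds exactly.
* The Wilcoxon signed-rank test drops zero differences, uses midranks for
  ties, enumerates the exact null for $n \le 25$ (rank-sum recursion with
  doubled ranks so midranks stay integral), and returns $p = 1$ by
  convention when every difference is zero.
* Lesion bone/soft classification uses Euclidean distance in mm from the
  lesion boundary to the nearest bone voxel (bone iff ≤ 10 mm or inside
  bone); "in-plane with the implant" is read as axial-slice-range overlap
  with the implant mask, since no operational definition is given.
* Training aborts with a diagnostic on a non-finite loss; implant cases
  are refused in training by default (`allow_implant = TRUE` overrides,
  and the pipeline refuses a configuration that requests implants in the
  training set outright).

## Known limitations

* 2-D parallel-beam geometry with an inverse-crime system model (the same
  matrix simulates and reconstructs): adequate for algorithmic
  properties, silent on scanner-geometry effects, scatter, randoms and
  normalization.
* The phantom family is low-entropy; a network trained on it generalises
  to nothing but it. That is intentional — it makes the
  out-of-distribution contrast crisp — but it means absolute variance
  levels, RMSE values and SUV biases reported by the acceptance script
  characterize the desk-scale conditions, not patients.
* The attenuation update's monotonicity guarantee holds for zero
  background and one subset; the ordered-subsets schedule trades that
  guarantee for speed exactly as ordered-subsets methods usually do.
* The sigmoid's fixed constants presume clinical variance magnitudes
  (implant-region variances around $10^5$ HU² against an in-body band of
  0–2.5×10⁴). The desk-scale network's absolute variances are much
  smaller — its halo medians fall below the sigmoid's transition
  midpoint — so although the halo-to-soft-tissue variance *ratio* is
  enormous (10³–10⁵), the post-sigmoid $\beta$ contrast between halo and
  normal tissue is weaker than clinically. The implant-recovery
  experiment therefore fixes the prior construction (air-filled prior in
  the halo, $\beta = 10^3$ there, $5\times 10^6$ elsewhere) as its study
  condition; the acceptance script reports the fully network-driven
  variant alongside it for comparison.
* Per-volume min–max rescaling of the weight map makes $\beta_{MR}$
  depend on each volume's variance range; a volume whose maximum variance
  is "only" moderately high still maps it to $\beta_{min}$. The fixed
  mapping avoids this at the cost of never reaching $\beta_{max}$; both
  readings are available because the choice is genuinely underdetermined.
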