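# upctmlaa

Uncertainty-guided pseudo-CT priors for joint PET activity and attenuation
reconstruction, at desk scale.

## The problem

Quantitative PET requires attenuation correction at 511 keV, but MRI measures
spin density, not electron density: a pseudo-CT synthesized from Dixon MR
channels is the standard workaround in PET/MRI. Pseudo-CT regression fails
exactly where it matters most — metal implants produce a signal void in MRI
(so the network sees "air") while the true attenuation is the highest in the
field of view, and rare anatomy is extrapolated silently. Joint
maximum-likelihood estimation of activity and attenuation (MLAA) can recover
attenuation from the emission data alone, but is noisy and suffers
activity/attenuation crosstalk.

This package implements a framework that couples the two: a
dropout-equipped convolutional pseudo-CT regressor is sampled with Monte
Carlo Dropout, giving a pseudo-CT estimate *and* a voxelwise predictive
variance. Where the network is confident, a strong quadratic prior pins the
MLAA attenuation estimate to the pseudo-CT; where the network is uncertain
(implants, artifacts), the prior is weak and the emission data dominate.

## The model

Monte Carlo Dropout over `N` stochastic forward passes `f_i(x)` gives

    pCT = (1/N) sum_i f_i(x),      sigma^2 = (1/N) sum_i (f_i(x) - pCT)^2 .

The variance (HU^2) is mapped to a weight in (0,1) by the fixed sigmoid

    w(r) = 1 / (1 + exp(0.1 (sigma^2(r)/1000 - 25)))

and affinely rescaled over in-body voxels to the prior-strength range
`beta_MR in [1e3, 5e6]` (zero outside the body). Reconstruction alternates
TOF-OSEM activity updates with ordered-subsets transmission-style (OSTR)
attenuation updates that maximize the Poisson emission likelihood penalized
by

    R_MR(mu) = sum_i (beta_MR,i / 2) (mu_i - mu_MR,i)^2   +   beta_smooth * R_smooth(mu)

where `mu_MR` is the bilinear HU-to-mu conversion of the pseudo-CT, with
5 outer iterations of 1 OSEM pass + 5 OSTR passes and
`beta_smooth = 2e4`. Everything runs on seeded synthetic pelvis-like
phantoms (including metal-implant cases) generated by the package itself, so
the whole chain is testable without any data download.

## Worked example

```r
library(upctmlaa)

# implant-free training phantoms and an implant test case
ds <- make_dataset(6, phantom_spec(seed = 1), seed = 21)
icase <- make_phantom(phantom_spec(
  implant_spec = list(center = c(0, 15, 20), radius_mm = 10,
                      hu = 3000, halo_mm = 24),
  seed = 99))

# train the pseudo-CT regressor (implant-free policy is enforced)
model <- bcnn_train(ds,
  net_config(depth = 3, base_channels = 8, dropout = 0.2, patch = c(32, 32)),
  train_config(lr = 1e-3, iterations = 600, seed = 5))

# Monte Carlo Dropout: pseudo-CT + predictive variance
mc <- mc_dropout_infer(model, icase$mr[1, , , ], mc_config(32, seed = 3))
halo <- icase$halo_mask[1, , ]
soft <- icase$labels[1, , ] == 2 & !halo
median(mc$variance[halo]) / median(mc$variance[soft])
#> [1] 641.1096
```

The ratio says the network's predictive variance inside the metal-artifact
halo (a structure it never saw in training) is orders of magnitude above
normal soft tissue — the out-of-distribution signal that drives the
spatially varying prior:

```r
body    <- body_mask(mc$pct)
betamap <- weight_to_beta(variance_to_weight(mc$variance), body)
range(betamap[body])
#> [1] 1e+03 5e+06
```

Reconstruction then recovers the implant from the emission data while the
prior holds elsewhere. The prior here is the controlled construction the
implant experiment is defined on — the attenuation map with the halo read
as air (what an MR-only regressor yields on a signal void), a weak prior
(1e3) inside the halo and a strong prior (5e6) elsewhere (seeded 64 x 64
single-slice run, 1e7 counts):

```r
sys  <- pet_system(scanner_geometry(), dim(icase$ct)[2:3], 3)
mu   <- hu_to_mu(icase$ct[1, , ])
sino <- simulate_emission(icase$activity[1, , ], mu, sys,
                          total_counts = 1e7, seed = 7)
halo2d <- icase$halo_mask[1, , ]
bpct <- icase$ct[1, , ]; bpct[halo2d] <- -1000
beta_air <- matrix(5e6, 64, 64); beta_air[halo2d] <- 1e3
beta_air[!icase$body_truth[1, , ]] <- 0
fit <- mlaa_run(sino, sys, "upct", recon_config(), icase$body_truth[1, , ],
                betamap = beta_air, mu_mr = hu_to_mu(bpct))
mean(fit$mu[icase$implant_mask[1, , ]]) / mean(mu[icase$implant_mask[1, , ]])
#> [1] 0.8427902
```

i.e. the mean attenuation coefficient recovered in the implant core is
within ~16% of the truth, even though the pseudo-CT prior there said "air".
(The vignette discusses why, at desk scale, the beta map fed to this step
is fixed by construction rather than taken from the tiny network's
variance map, whose absolute magnitudes fall below the sigmoid's clinical
transition band.)

A full comparator run (OSEM with true and pseudo-CT attenuation, naive MLAA,
uniform-beta MLAA, uncertainty-weighted MLAA, plus lesion SUVmax and
masked error reports) is available as a single call:

```r
res <- run_pipeline(run_config(), out_dir = "run1")
res$report
```

A thin command-line wrapper is shipped at `inst/cli/pipeline.R`.

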