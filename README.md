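# omtapc

Density-weighted optimal-mass-transport (OMT) tensorization of masked 3D
brain volumes, and an algebraic preclassification (APC) model for the
resulting tumor tensors.

## What it does

Brain MRI occupies an irregular region of a scan, while the models that
consume it want regular cubic tensors. `omtapc` converts a skull-stripped,
masked volume into an `m^3` tensor by a measure-preserving change of
coordinates built on a tetrahedral mesh of the brain voxels:

* a **mass-preserving map** `f_rho : M -> B` carries the brain onto the unit
  ball under the density `rho_gamma(v) = exp(gamma * He(v))` inside the
  whole-tumor (WT) region and `1` elsewhere (`He` = histogram-equalized
  intensity in [0,1]); the per-tet constraints are
  `rho(tau) |tau| = |f(tau)|`;
* a **volume-preserving map** `f : C -> B` carries the reference cube (side
  `(4*pi/3)^(1/3)`) onto the ball;
* the composition `f^(-1) o f_rho : M -> C` lands the brain in the cube,
  where a regular grid is resampled into the OMT tensor.

Raising `gamma` inflates the tumor's mass, hence its share of the tensor —
a controlled zoom on the lesion that keeps the global anatomy. The APC
model then crops the WT region to an `m^3` tumor tensor, extracts
truncated-SVD features `x(s) = vec(U_j S_j)` from its three mode
unfoldings, and fits multiview orthonormalized partial least squares
(MvOPLS): maximize `tr(P' A P)` s.t. `P' B P = I_k` with `A = X Y' Y X'`,
`B = blockdiag(X_s X_s' + gamma_s I)`, solved as a generalized eigenvalue
problem; test subjects get six algebraic probability preclassifications
`y_t(s) = W*' P*(s)' x_t(s)` (3 modes x 2 modalities).

A deterministic phantom generator (ellipsoidal brains, spherical tumors,
class-dependent intensity effects), classification/segmentation metrics
(AUC, ACC, SENS, SPEC, PPV, NPV, F1, Dice, HD95) and an end-to-end pipeline
driver make every stage testable without clinical data. It is aimed at
researchers studying transport-based normalization and algebraic feature
pipelines for volumetric imaging.

## Worked example

```r
library(omtapc)

# a 32^3 two-modality phantom with a planted tumor
spec <- phantom_spec(grid_shape = c(32L, 32L, 32L), brain_axes = c(12, 10.5, 9.5),
                     tumor_center = c(20, 18, 16), tumor_radius = 4,
                     class_label = 1L, effect_size = 3, seed = 7L)
vol <- generate_phantom(spec)
vol
#> <voxel_volume> 32x32x32 voxels, 4976 brain, 280 WT, spacing 1x1x1 mm

# transport it into a 32^3 OMT tensor at two density exponents
t1 <- omt_tensorize(vol, gamma = 1.0,  m_hat = 32L, cube_resolution = 10L)
t2 <- omt_tensorize(vol, gamma = 1.75, m_hat = 32L, cube_resolution = 10L)
c(wt_fraction(t1), wt_fraction(t2))
#> [1] 0.2168274 0.3399658
```

The whole-tumor share of the tensor grows with `gamma`: at `gamma = 1.75`
the tumor occupies about 1.6x more of the tensor than at `gamma = 1.0`,
while the total transported mass stays exactly `4*pi/3`.

```r
# end-to-end synthetic benchmark: 60 subjects, 3-SD class effect, 80/20 split
res <- run_pipeline(default_pipeline_config())
res$report
#> <metrics_report> n=12 thr=0.5 | AUC 1.0000 ACC 1.0000 SENS 1.0000 SPEC 1.0000 PPV 1.0000 NPV 1.0000 F1 1.0000
#>   counts TP=6 FP=0 TN=6 FN=0
```

A planted 3-noise-SD tumor effect is recovered perfectly on the held-out
split; with `effect_size = 0` the held-out AUC stays near 0.5 (no leakage).

## Command line

A thin CLI over the same functions lives at `inst/cli/omtapc`:

```sh
Rscript inst/cli/omtapc simulate --n 10 --effect-size 3 --out phantoms
Rscript inst/cli/omtapc tensorize --in s001_ch1.nii.gz --brain-mask s001_brain.nii.gz \
    --wt-mask s001_wt.nii.gz --gamma 1.75 --m-hat 64 --out s001_omt
Rscript inst/cli/omtapc run --out run1
```

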