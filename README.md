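# embryoqp

Label-free embryo health profiling from quantitative phase z-stacks.

Preimplantation embryo quality is normally graded by eye from brightfield
morphology. Quantitative phase imaging (QPI) measures the optical path-length
delay φ(**r**) through the sample, which is linearly related to its
non-aqueous ("dry") mass: for a region of interest,

    M = λ / (2πγ) ∫ φ(r) d³r

with λ the illumination wavelength and γ the refractive increment
(≈ 0.2 µm³/pg for protein). Given a co-registered nucleus channel (stained
fluorescence or a label-free nucleus prediction), each nucleus of a day-5
embryo can therefore be characterised by structural descriptors (volume V,
surface area S, sphericity Sp = π^{1/3}(6V)^{2/3}/S) and compositional ones
(dry mass M, dry-mass density ρ = M/V), and the embryo as a whole by its
nucleus count and by the spatial organisation of its nuclei.

`embryoqp` implements that pipeline end to end for researchers working with
phase tomography of embryos (and for anyone who wants a tested reference
implementation of its parts):

* **Phase reconstruction** — four-frame phase-shifting reconstruction
  (`reconstruct_gradient()`) and spectral integration of the phase gradient
  along the shear axis (`integrate_gradient()`).
* **3D nucleus instance segmentation** — per-section median filtering, dual
  (hard + adaptive) thresholding, morphological cleanup and watershed
  splitting (`segment_slice()`), then z-trajectory linking of 2D objects,
  splitting of axially stacked nuclei, 3D morphological filters and
  isotropic resampling (`segment_stack()`, `resample_isotropic()`). The
  published cut-offs (19 px median window, 0.2 hard threshold, 0.55/145 px
  adaptive threshold, 400 px² minimum area, 60 px/0.8 small-object filter,
  50 px link radius, 5 µm gap limit, 5000–250000 voxel volume window,
  z-depth ≥ 3, extent ≥ 0.14 at 11 px/µm, 1 µm z-step) are the defaults of
  `seg2d_params()` / `link3d_params()` and rescale automatically to other
  calibrations.
* **Feature extraction** — `dry_mass()`, `shape_features()` (isosurface
  area via marching tetrahedra on the signed distance field),
  `build_records()`, trophectoderm/inner-cell-mass assignment at the 0.7
  normalized-radius threshold (`assign_compartment()`), the normalized mean
  dry-mass-density map (`dmd_map()`) and the nucleus count map
  (`count_map()`).
* **Scattering-spectrum biomarker** — the embryo modelled as identical unit
  spheres at the nucleus centroids; the radially averaged 3D Fourier power
  spectrum of that point model yields the half-power bandwidth `bw3dB`
  (`scattering_bandwidth()`), which is larger for compact, growth-arrested
  embryos than for expanded blastocysts.
* **Health grading** — a feature-based classifier (5→10→2→2 network with
  ReLU hidden layers and softmax output, L-BFGS training with L2 penalty
  1e-6 and early stopping; `train_fbm()`), per-nucleus predictions
  aggregated to embryo grades by max-voting (`max_vote()`), and the sparse
  z-subset protocol that refuses fewer than 7 slices or spacings above
  10 µm (`sparse_vote()`).
* **Evaluation metrics and statistics** — PSNR, multi-scale structural
  similarity, Pearson loss and their (2, 1, 0.5) combination loss for
  nucleus-channel predictors; a Lilliefors-gated group-comparison pipeline
  (Kruskal–Wallis + Dunn–Holm or Levene/ANOVA + t–Holm) and the TE/ICM
  density test at α = 1e-4.
* **Synthetic embryos** — `generate_embryo()` / `generate_cohort()` render
  blastocyst-like and growth-arrested embryos with exact ground truth
  (per-nucleus density, volume, dry mass, compartment), so every stage is
  testable without real data.

## Worked example

Simulate a healthy blastocyst, segment its nucleus channel, and extract
features:

```r
library(embryoqp)

cfg <- synth_config("blastocyst_healthy",
  lateral_px_per_um = 2.5, z_step_um = 0.4, seed = 42)
e  <- generate_embryo(cfg)              # phase + channel + ground truth
lv <- segment_stack(unclass(e$channel),
  seg2d_params(lateral_px_per_um = 2.5),
  link3d_params(lateral_px_per_um = 2.5, z_step_um = 0.4), verbose = TRUE)
#> segment_stack: 1039 2D objects -> 92 trajectories -> 59 nuclei
nrow(e$truth)                           # 60 true nuclei
ef <- analyze_embryo(lv, e$phase, scatter_grid = 128)
ef$nuc_count                            # 59
round(ef$bw3dB, 4)                      # 0.0573 rad/um
head(ef$records[, c("volume_um3", "sphericity", "dry_mass_pg",
  "dmd_pg_per_um3", "compartment")], 3)
#>   volume_um3 sphericity dry_mass_pg dmd_pg_per_um3 compartment
#> 1      310.6     0.9829      21.150        0.06810          TE
#> 2      147.6     0.9483       8.832        0.05982          TE
#> 3      239.4     0.9836      16.512        0.06898          TE
te_icm_test(ef$records)
#> <group_comparison> dmd_pg_per_um3 | KW | omnibus p = 2.13e-10 (alpha 0.0001) *
```

59 of 60 nuclei are recovered at this reduced sampling, per-nucleus
densities sit near the configured 0.05 (core) / 0.0625 (shell) pg/µm³, and
the trophectoderm-vs-inner-cell-mass density contrast is highly significant
— the blastocyst signature. A growth-arrested embryo
(`synth_config("cleavage_sick")`) shows fewer nuclei, a wider scattering
spectrum and no compartment contrast.

A thin command-line interface with subcommands (`simulate`, `reconstruct`,
`segment`, `features`, `scatter`, `train-fbm`, `grade`, `evaluate`,
`stats`) is installed at `system.file("cli/embryoqp", package = "embryoqp")`.

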