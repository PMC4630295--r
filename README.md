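# phasereg

Suppression of large draining-vein contributions to gradient-echo BOLD fMRI
using the complex-valued signal.

Gradient-echo BOLD is biased toward large veins: voxels on or near a
draining vein show strong task responses that reflect pooled blood from a
wide territory, not local neural activity. Task-related *phase* changes,
however, come almost exclusively from large veins, while microvascular
activity is magnitude-only. Phase regression removes the phase-predictable
part of each voxel's magnitude timecourse:

- **PR** (phase regressor): fits `S^m ~ b0 + b1 S^p` under a chi-squared
  loss `Σ (S^m − b0 − b1 S^p)² / (σ_m² + b1 σ_p²)` with a closed-form root
  for `b1*`. Because `b1` appears in the denominator, `b1*` is biased
  upward: PR over-suppresses, even in voxels with no vein.
- **sPR** (source-localized phase regressor): uses the unbiased OLS loss
  (slope = correlation for z-scored series) and picks the phase source
  `k*` with maximal `|corr(S^m_i, S^p_k)|` from the voxel plus its six
  face-adjacent neighbours — because a voxel-sized vein puts its coherent
  phase response in the *adjacent* voxels, not in the vein voxel itself.
  The suppressed signal is `S^m_i − corr(S^m_i, S^p_k*) · S^p_k*`.

The package is aimed at researchers working with paired magnitude/phase
fMRI reconstructions (or wanting to validate suppression methods before
acquiring them). It provides:

- single-voxel simulation of complex-valued block-design BOLD at specified
  expected fSNR, and the full PR/sPR suppression grid (`simulate_voxel()`,
  `run_grid()`);
- the closed-form PR fit, the sPR fit, and whole-volume split-run
  suppression (`fit_pr_chisq()`, `fit_spr()`, `suppress_volume()`);
- a physics-based vein phantom: infinite-cylinder susceptibility field
  (`offres_field()`), intravoxel dephasing with task-modulated blood
  oxygenation (`synthesize_phantom()`), and venogram minimum-intensity
  projection (`venogram_mip()`);
- preprocessing: slice-wise homodyne phase filtering, cubic detrending,
  z-scoring (`homodyne_filter()`, `preprocess_series()`);
- ROI statistics: delay-aware contrast t-maps, threshold-and-cluster ROI
  definition, vein-contribution and laterality metrics (`contrast_tmap()`,
  `define_roi()`, `vein_contribution()`, `laterality()`);
- NIfTI pair I/O and a command-line interface (`read_complex_series()`,
  `inst/cli/phasereg.R`).

## Worked example

Simulate a voxel containing a large vein — strong task response in both
magnitude and phase — then suppress it both ways:

```r
library(phasereg)

tc <- simulate_voxel(mag_fsnr = 5, phase_fsnr = 5, seed = 42)
d  <- block_design()          # 14 x 16 s off/on blocks at 1 s sampling
Sm <- zscore(tc$magnitude)
Sp <- zscore(tc$phase)

realized_fsnr(Sm, d)          # 4.91  -- realized magnitude "t"
realized_fsnr(Sp, d)          # 5.27  -- realized phase "t"

fit <- fit_pr_chisq(Sm, Sp)
fit
#> <pr_fit> b1* = 0.9344 (r = +1, corr = 0.871, minimizer coefficients)

realized_fsnr(apply_pr(Sm, Sp, fit), d)                 # 0.21
realized_fsnr(apply_spr(Sm, Sp, cor(Sm, Sp)), d)        # 0.47
```

Both methods flatten the vein-driven response (t ≈ 5 → t ≈ 0.2–0.5); PR
suppresses slightly harder because its chi-squared loss overestimates
`b1*` (here 0.93 vs the OLS slope 0.87). The difference matters in the
opposite regimes: with magnitude-only signal PR degrades the response it
should preserve, and with phase-only signal PR manufactures an artifactual
response; sPR does neither. `run_grid(step = 0.1, seed = 1)` maps all of
this over the full 101 × 101 fSNR plane (20,402 simulations, seconds) and
`autoplot()` draws the two heatmaps.

For volume data, the pipeline is

```r
series <- read_complex_series("run2_mag.nii.gz", "run2_phase.nii.gz")
train  <- read_complex_series("run1_mag.nii.gz", "run1_phase.nii.gz")
pre_te <- preprocess_series(series)   # homodyne -> detrend -> z-score
pre_tr <- preprocess_series(train)
sup    <- suppress_volume(pre_tr, pre_te, method = "sPR", neighborhood = 7)
tmap   <- contrast_tmap(sup, design)  # pooled t with 6 s delay from design
rois   <- define_roi(tmap, threshold = 3)
vein_contribution(define_roi(contrast_tmap(pre_te, design))$right, rois$right)
```

with fits always estimated on one run and applied to the other. The
`phantom_single_vein()` and `phantom_two_vein()` generators produce
synthetic data with known ground truth for exercising exactly this
pipeline; `make_fixtures()` writes them to disk.

## Command line

```sh
Rscript inst/cli/phasereg.R simulate-grid --method spr --step 0.1 --seed 1 --out grid.csv
Rscript inst/cli/phasereg.R phantom --type single --seed 1 --out phantom/
Rscript inst/cli/phasereg.R preprocess --mag mag.nii.gz --phase phase.nii.gz --out pre/
Rscript inst/cli/phasereg.R suppress --train-mag ... --test-mag ... --method spr --out sup/
Rscript inst/cli/phasereg.R roi-metrics --tmap-mag t1.nii.gz --tmap-spr t2.nii.gz --out metrics.csv
```

Exit codes: 0 success, 2 configuration error, 3 data/I-O error. Every
subcommand logs the package version, resolved flags, and master seed; all
randomness derives from `--seed`.

See the vignette (`vignettes/phase-regression.Rmd`) for the model details,
the phantom's physics and calibration, and the package's design decisions.
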