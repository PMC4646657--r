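# mgdf — multi-feature Gaussian distribution fitting active contours for vessel segmentation

`mgdf` segments thin curvilinear structures — retinal blood vessels in
particular — in 2-D grayscale or RGB images.  It is aimed at
biomedical-image analysts who need a classical (non-learned),
parameter-transparent vessel segmenter that copes with intensity
inhomogeneity, plus the standard baselines and evaluation metrics to
compare against, and seeded synthetic phantoms so everything is testable
without any external dataset.

## The model

Two feature channels are modelled jointly:

- **Vesselness** `V(x) ∈ (−1, 1)`: a bank of oriented quadrature
  log-Gabor pairs (even = line filter, odd = edge filter; centre
  frequency 5π/7, 2-octave bandwidth, 3 scales, 15×15 kernels) gives
  per-scale complex responses `q_m = Σ_j (e_mj + |o_mj| i)`.  These are
  combined as `P = Σ_m q_m |q_m|^β / Σ_m |q_m|^β` and normalised to
  `V = P·|P| / (P² + α²)`: positive inside bright tubes, ~0 at their
  edges, negative in the surround.

- **Intensity** `I(x)` on the 0–255 scale.

Each feature, in each region (vessel interior where the level-set field
`φ < 0`, exterior where `φ > 0`), is fitted by local Gaussians with
spatially varying mean `u_i(x)` and standard deviation `s_i(x)` computed
under a truncated Gaussian window `w` (σ = 3, 15×15).  Segmentation
minimises

```
E = Σ_i ∫∫ w(x−y) [ λ_iI (−log p_iI(I(y))) + λ_iV (−log p_iV(V(y))) ] H_i(φ(y)) dy dx
  + υ ∫ |∇H_ε(φ)|  +  μ ∫ ½(|∇φ| − 1)²  +  η ∫ γ^κ / (γ^κ + |φ|^κ)
```

by forward-Euler gradient descent.  Because the Gaussian statistics are
local, smooth bias fields are absorbed into `u_i(x)`; the vesselness
channel contributes a contrast-independent witness for faint thin
vessels.  Nulling the vesselness weights recovers the single-feature
local-Gaussian (LGDF) model exactly; Chan–Vese (global means) and
local-binary-fitting (LBF) baselines share the same evolution engine.

## Worked example

```r
library(mgdf)

ph  <- generate_vessel_phantom(default_phantom_spec(seed = 1))  # 128x128, 3 tubes,
                                                                # bias 0.25, noise 3
v   <- enhance(ph$image)          # local-phase vesselness map in (-1, 1)
res <- evolve(ph$image, v)        # MGDF level-set evolution
res
#> <MGDF segmentation> 128x128, 44 iterations (converged), interior 1794 px

dice_score(res$mask, ph$truth)
#> [1] 0.95637
performance_metrics(confusion_counts(res$mask, ph$truth))
#> Se 1.000  Sp 0.990  Acc 0.991  Auc 0.995
```

All 1644 true vessel pixels are recovered (Se = 1); the Dice of 0.956
reflects a thin residual halo of false positives around the tubes.
`res$energy` holds the per-iteration energy breakdown (data terms,
length, distance and small-component regularisers).

Model comparison on the same inputs:

```r
m0 <- vesselness_init(v)                       # shared initial region
segment_lgdf(ph$image, init = m0)              # intensity-only local Gaussians
segment_cv(ph$image, init = m0)                # global two-phase means
segment_model(ph$image, "lbf", seeds = list(list(center = c(64, 64), radius = 16)))
```

## Command line

A thin wrapper over the same functions is installed at `exec/mgdf`:

```sh
mgdf phantom  --out-image ph.png --out-truth truth.png --seed 7
mgdf enhance  --image ph.png --out vessels.tif
mgdf segment  --image ph.png --vesselness vessels.tif --out-mask mask.png --log energy.csv
mgdf evaluate --pred mask.png --truth truth.png --out report.csv
```

All tunables are available as flags or through `--config file.yml`
(flat YAML, same keys as `mgdf_config()`; flags win).  Runs echo the
fully resolved configuration to stderr, and identical arguments plus
seed give byte-identical outputs.

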