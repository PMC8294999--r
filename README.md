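# hotspotseg

Detection and segmentation of metastatic "hot spots" — focal bright lesions —
in 2-D spinal MRI slices, for researchers building or benchmarking
computer-aided diagnosis pipelines for vertebral bone metastasis.

The package implements a four-stage cascade:

1. **Sparse-coding features.** Patches \(x_i\) of side \(l\) are drawn from
   the image and a dictionary \(\{\phi_j\}_{j=1}^m\) of unit-norm atoms is
   learned by alternating minimization of
   \(\min_{c,\phi} \sum_i \lVert x_i - \sum_j c_{ij}\phi_j \rVert_2^2
   + \lambda \sum_{ij} |c_{ij}|\)
   (lasso coding by coordinate descent, exact per-atom unit-sphere updates).
   An image-level descriptor is the max- and mean-pool of the absolute codes.
2. **AdaBoost triage.** Discrete AdaBoost over depth-3 CART weak learners
   produces a signed confidence \(\mathrm{Result} = \sum_t \alpha_t h_t(x)\),
   \(\alpha_t = \tfrac12\ln\frac{1-\epsilon_t}{\epsilon_t}\). A band of
   half-width \(\theta\) splits decisions into three levels:
   \(\mathrm{Result} > \theta\) → level I (certain hot spot),
   \(\mathrm{Result} < -\theta\) → level III (no hot spot, cascade halts),
   \(|\mathrm{Result}| \le \theta\) → level II (uncertain, treated as
   suspicious).
3. **MILBoost hot-spot scanning.** A multi-instance boosted stump ensemble
   is trained from bag-level labels only (a positive bag needs at least one
   positive instance) under the negative-log-likelihood loss
   \(\mathrm{Loss} = -\sum_j [\mathbf 1(y_j{=}1)\log p_j +
   \mathbf 1(y_j{=}-1)\log(1-p_j)]\) with the noisy-OR bag rule
   \(p_j = 1 - \prod_l (1 - p_{jl})\), \(p_{jl} = \sigma(m(x_{jl}))\).
   A sliding-window scan turns instance scores into a per-pixel hot-spot
   probability map.
4. **Chan–Vese level-set segmentation.** The probability map is binarized at
   \(\rho\) into the initial field \(\phi = \mp g\) (inside is
   \(\{\phi \le 0\}\)) and evolved by explicit Euler steps
   \(\phi^{c+1} = \phi^c + \Delta t\, \partial\phi^c/\partial t\) minimizing
   \(\lambda_a \int_{\Omega_a} (P - g_a)^2 + \lambda_b \int_{\Omega_b}
   (P - g_b)^2\) with \(\Delta t = 0.13\), \(g = 0.5\).

Otsu thresholding and seeded region growing are included as baseline
segmenters, and Dice / Jaccard scoring
(\(D = 2|M\cap N|/(|M|+|N|)\), \(J = |M\cap N|/|M\cup N|\)) compares all
three. Because no clinical dataset is publicly available, a phantom module
generates synthetic spine-like slices (banded background, bias field,
Gaussian noise, planted elliptical lesions) with exact ground truth and a
three-level gold labelling mirroring a radiologist panel.

## Worked example

```r
library(hotspotseg)

spec   <- phantom_spec(height = 96, width = 96, n_hotspots = 2,
                       hotspot_radius_range = c(4, 9))
cohort <- generate_cohort(c(14, 6, 10), spec, seed = 1)   # I / II / III
cfg    <- pipeline_config(l = 8L, m = 16L, adaboost_T = 30L, mil_T = 30L,
                          stride = 2L, feature_stride = 4L, seed = 1L)
models <- train_pipeline(cohort, cfg, n_patches = 4000L, dict_iters = 10L)
models
#> <hotspot_models>
#>   <sc_dictionary> 16 atoms of length 64, lambda 0.1, 10 alternation(s), final objective 718.614
#>   <adaboost_model> 1 round(s), final training error 0, theta 11.51
#>   <mil_model> 11 stump(s), rule noisy-or, 17 feature(s)

case <- generate_phantom(spec, seed = 99)
res  <- run_pipeline(case$image, models)
res
#> <pipeline_result> triage level I (margin 11.5); mask with 348 pixel(s)
overlap_scores(case$mask, res$mask)[["dice"]]
#> [1] 0.9957

neg <- generate_phantom(phantom_spec(height = 96, width = 96, n_hotspots = 0),
                        seed = 7)
run_pipeline(neg$image, models)
#> <pipeline_result> triage level III (margin -11.5); halted, no segmentation
```

The triage level decides the flow: level III halts with no probability map
and no mask; levels I and II are scanned and segmented. The Dice of 0.996
says the level-set mask almost exactly matches the planted lesions.
`autoplot()` methods visualize phantoms, probability maps, segmentations and
benchmark reports; `tidy()`/`glance()` expose boosting traces.

A thin command-line wrapper lives at `inst/cli/hotspotseg.R`
(`phantom | train | run | evaluate` subcommands over PNG/CSV images, CSV
manifests, YAML configs and JSON models).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full cascade from scratch: it generates a training and a
held-out phantom cohort from the given seed, trains dictionary, triage and
MIL models, triages every held-out slice, segments the detected ones with
the level set and both baselines, and prints the triage confusion table and
the per-method mean Dice / Jaccard table.
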