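# cineclust

Motion-aware lesion analysis for cardiac cine-MRI, built around
spatio-temporal consistency clustering — and exercised end to end on a
synthetic beating-heart phantom, so every stage is testable on a single
CPU without clinical data.

## Who this is for

Researchers prototyping unsupervised lesion-candidate detection on cine
sequences: myocardial lesions (infarct, edema) alter both local
appearance and local contractility, and this package turns those two
cues into a pixel partition with quality scores, plus the loss terms a
larger learning system would attach around it.

## The method

For a frame sequence `{X_t}` over one cardiac cycle:

1. **Dense optical flow** `V_t` between consecutive frames
   (deterministic coarse-to-fine Horn–Schunck; backward convention
   `X_{t+1}(x) ≈ X_t(x + V_t(x))`).
2. **Motion-consistency integral**
   `I_motion(x) = Σ_t ‖∇V_t(x)‖² Δt` — zero for coherently moving
   tissue, large at lesion-induced motion heterogeneity. Cyclic
   contraction peaks are removed first by **phase normalization**
   (frame pairs above the 0.8 energy quantile are excluded).
3. **Hybrid descriptor** `D_s = λ_s·S + λ_t·I_motion` with `S` the
   temporal mean intensity, both z-scored (`λ_s = λ_t = 0.5`).
4. **Spectral clustering** on the Gaussian affinity
   `W_ij = exp(−|D_s(i) − D_s(j)|² / 2σ²)` (`σ = 1.5`, local
   neighbourhood) via the combinatorial Laplacian `L = D − W`,
   followed by **DBSCAN refinement** (`ε = 2.5` px, min 5 points) that
   splits disconnected fragments and labels sparse ones noise.
5. **Metrics and losses**: Dice/IoU, sensitivity/F1, cluster entropy
   and compactness, motion-compensated temporal consistency, partition
   concordance, PSNR/SSIM, and the weighted objective combining
   adversarial, SSIM, pathology-KL, motion, Laplacian-topology
   (`λ_topo = 0.2`) and curriculum terms (difficulty threshold δ
   annealed 0.5 → 0.1 over 50 epochs).

The synthetic phantom renders a sinusoidally contracting annular
myocardium analytically, so its ground-truth flow is exact; lesions are
discs with configurable intensity shift and motion damping. See the
methods vignette (`vignettes/cineclust-methods.Rmd`) for every design
decision and limitation.

## Worked example

```r
library(cineclust)
res <- run_pipeline(pipeline_config(seed = 7))
res$metrics[, c("dice_best", "iou_best", "cluster_entropy",
                "compactness_pct", "temporal_consistency",
                "psnr_db", "ssim")]
#>   dice_best iou_best cluster_entropy compactness_pct temporal_consistency
#> 1     0.799    0.665           1.485           14.74                0.993
#>   psnr_db  ssim
#> 1  31.168 0.751
```

Reading: on a 128 × 128, 20-frame phantom with one lesion (intensity
delta 0.2, motion damping 0.8), the best-matching refined cluster
overlaps the true lesion with Dice 0.80; ground-truth lesion masks
carried along the estimated flow overlap frame-to-frame at 0.99; the
bicubic-degraded copy of the sequence scores 31.2 dB PSNR / 0.75 SSIM
against the original. Entropy (nats, soft memberships) and compactness
(explained descriptor variance) are definition-dependent quality scores
— comparable within this package only.

`res$losses` prints the weighted objective; `run_pipeline(...,
output_dir = "out")` additionally writes NIfTI sequences and label
maps, `losses.json`, `metrics.csv` and a re-executable
`manifest.yaml`.

A thin CLI wraps the same functions:

```sh
exec/cineclust simulate --out out --seed 3
exec/cineclust cluster --in out/sequence.nii.gz --out out/labels.nii.gz \
    --sigma 1.5 --eps 2.5 --min-samples 5 --k 6
exec/cineclust run-all --out out --seed 3
```

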