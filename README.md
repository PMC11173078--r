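# octanomaly

One-class anomaly **detection** and **localization** for retinal optical
coherence tomography (OCT) B-scans, for researchers who have plenty of
healthy scans and no lesion-level labels. The package learns what healthy
retinal tissue looks like and flags — and spatially localizes — whatever
departs from it: choroidal neovascularization (CNV), diabetic macular
edema (DME), drusen, or anything else unseen.

## The method

Healthy scans are embedded as grids of *local-region* feature vectors: two
intermediate blocks of a convolutional backbone are locally average-pooled,
the coarser upsampled to the finer lattice, and concatenated, so cell
(r, c) holds an embedding `x_rc ∈ R^D` of one retinal region. All healthy
regions form a nominal bank `B`. A test region is scored by its average
k-nearest-neighbour distance

    s(x) = (1/k) Σ_{y ∈ kNN_B(x)} ‖x − y‖ ,   k = 5,

searched **globally** over all spatial positions (retinal scans are not
aligned or centered). The scan-level score is `max_rc s(x_rc)` — one small
lesion is enough — and upsampled, smoothed region scores form the anomaly
heat map. Supporting backends under the same interface:

* **greedy k-center coreset** — compresses the bank to 1–10 % with a
  farthest-point 2-approximation;
* **per-position Gaussians** — `s(x) = sqrt((x−μ_rc)' Σ_rc^{-1} (x−μ_rc))`
  (Mahalanobis, alignment-assuming);
* **gallery retrieval** — kNN over whole-image embeddings first, then
  pooled region kNN against the retrieved scans only;
* **center-loss adaptation** — fine-tunes the backbone on healthy scans
  toward the frozen embedding center `c`, with an elastic-weight-
  consolidation penalty `λ Σ F_i (θ_i − θ_i^0)²` against forgetting.

A seeded synthetic OCT generator (layered curved bands, multiplicative
gamma speckle, three lesion phenotypes with exact ground-truth masks,
optional scanner margins) makes the whole pipeline testable offline; see
`vignettes/oct-anomaly-methods.Rmd` for the model, parameters and
limitations.

## Worked example

```r
library(octanomaly)

dir <- tempfile("oct")
generateDataset(dir, synthConfig(), nTrain = 40, nTestPerClass = 10,
                seed = 7)

config <- defaultRunConfig("global_knn", coresetFraction = 0.1)
model  <- octFit(file.path(dir, "train"), config, seed = 0)
scored <- octScore(model, file.path(dir, "test"), withMaps = TRUE)
ev     <- octEvaluate(scored$scores)

model
round(c(pooledAUC = ev$pooled$rocAuc, ev$perPathology), 3)
head(scored$scores, 3)
```

```
FittedModel backend 'global_knn', 40 training scans
pooledAUC       cnv       dme    drusen 
        1         1         1         1 
  sourceId label     score
1 cnv_0001   cnv 0.3732494
2 cnv_0002   cnv 0.4268475
3 cnv_0003   cnv 0.5294419
```

`pooledAUC` is the probability that a random anomalous scan outscores a
random healthy one (1.0 = perfect separation); the per-pathology entries
are one-vs-normal AUCs. Each scan's `score` is the maximum region kNN
distance; `scored$maps` holds the corresponding heat maps whose hot spots
sit on the injected lesions.

A command-line wrapper with `synth | fit | score | evaluate` subcommands
lives at `inst/scripts/octad.R`.

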