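# patchCellularity

Automated **tumour cellularity (TC)** estimation on hematoxylin-and-eosin
(H&E) breast-tissue patches after neo-adjuvant chemotherapy. TC — the
fraction of a patch's area occupied by malignant cells — feeds the
residual cancer burden grading of treatment response, and is normally
scored by a pathologist's eye, patch by patch. This package implements a
classical computer-vision pipeline that computes it automatically on
512 × 512 px patches at 20× magnification (0.5 µm/px), for image-analysis
researchers and for anyone who needs a fully inspectable, deterministic
baseline next to deep-learning approaches.

The pipeline, stage by stage:

1. **Colour separation** — per-pixel HSV triples are k-means-clustered
   (k = 3, seeded k-means++) into the pink stroma plane *Ip*, the blue
   nuclei plane *Ib* and the background plane *Iba*; a configurable HSV
   pink filter measures stroma concentration.
2. **Nuclei segmentation** — grayscale enhancement
   *In* = (K₁·*Io*⊙*Im* + K₂·*Io* + *Im*^0.1) / (K₁+K₂+1) with *Io* the
   luminance image and *Im* its 3×3 median filter, Otsu binarisation
   (dark class = nuclei, with contrast and haematoxylin-blueness gates
   for degenerate patches), and watershed splitting of touching nuclei
   on the distance transform. Validation by Jaccard index.
3. **Feature extraction** — per nucleus: geometry (area, perimeter,
   roundness 4πA/P², equivalent-ellipse axes, eccentricity,
   orientation), co-occurrence texture and mean HSV inside the cell
   body; per window (30/60/90/120 px): plane concentrations
   R = TW/TP, HSV means and 4-bin histograms; duct/cluster
   morphometrics; global concentrations. >150 values per nucleus.
4. **Key-parameter selection** — features aggregated on the
   TC ∈ {0, 0.1, …, 1} grid, kept when |Pearson r| ≥ 0.80 **and**
   lasso-selected, redundancy-pruned; a canonical 22-feature manifest
   ships with the package.
5. **Classification** — benign vs malignant nuclei by SVM, KNN or
   AdaBoost (100 depth-1 stumps) on the z-scored manifest.
6. **Cellularity** — malignant nuclei dilated by a 10 px disc
   (cytoplasm estimate); TC = covered area / total area. Batch mode,
   plus MSE/ICC(2,1) agreement evaluation.

A synthetic **phantom generator** (pink textured stroma, white fat,
benign/malignant elliptical nuclei, duct clusters) provides pixel-exact
ground truth — label maps, classes and a planted TC — so every stage is
tested end to end without clinical data.

## Worked example

```r
library(patchCellularity)

## a phantom with known ground truth
ph <- generatePhantom(phantomSpec(size = 256, nBenign = 25,
                                  nMalignant = 10, seed = 42))
ph
#> SyntheticPhantom: 256 x 256 px, 47 nuclei (10 malignant), true TC 0.1758

segmentNuclei(ph@patch)
#> NucleiLabelMap: 47 nuclei over 256 x 256 px

## train an SVM on phantoms spanning the cellularity range
train <- phantomSuite(c(0.1, 0.3, 0.5, 0.7, 0.9), nPerLevel = 1, seed = 91,
                      spec = phantomSpec(size = 256, nBenign = 30,
                                         nDucts = 0, fatFraction = 0.04))
tabs <- list(); cls <- list()
for (i in seq_along(train)) {
  p <- train[[i]]
  m <- matchToGroundTruth(segmentNuclei(p@patch), p)
  t <- extractFeatureTable(p@patch, patchId = paste0("t", i))
  tabs[[i]] <- t; cls[[i]] <- m$class[match(t$nucleus, m$nucleus)]
}
mod <- trainClassifier(do.call(rbind, tabs), unlist(cls), "svm", seed = 1)
mod
#> ClassifierModel <svm>: 22 features, seed 1
#>   training accuracy 1.000, TPR 1.000, AUC 1.000

## estimate TC on the held-out phantom
estimateCellularity(ph@patch, mod, patchId = "demo")
#> CellularityResult 'demo': TC = 0.1758 (10/47 nuclei malignant)
```

The estimate (0.1758) matches the planted TC (0.1758): all 47 nuclei
were recovered, the 10 malignant ones correctly classified, and their
dilated area fraction reproduces the ground-truth definition exactly.
The segmented nuclei count includes the 12 duct cells the default spec
plants alongside the 25 + 10 free nuclei.

A thin CLI wraps the same functions
(`exec/patchcellularity phantom|segment|extract|train|predict|evaluate`).

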