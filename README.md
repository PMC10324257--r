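# ocusiam

Siamese attention metric learning for two-class ocular ultrasound
classification.

On B-scan ocular ultrasound, **vitreous opacity (VO)** appears as
discrete echogenic spots while **posterior vitreous detachment (PVD)**
appears as a continuous echogenic membrane or arc. `ocusiam` implements
a complete pipeline that learns this distinction from small labeled
datasets:

1. **Preprocessing** — fixed fundus-window crop (x ∈ [100, 400),
   y ∈ [50, 300)), bilinear resize to the network input, channel-wise
   normalization x′ = (x − μ)/σ with the fixed shortcut μ = σ = 0.5,
   manifest management, 7:3 stratified splits, traditional augmentation.
2. **A siamese convolutional branch with sequential attention** — one
   shared parameter set embeds each image; after the last convolutional
   stage a channel gate
   M_c(F) = σ(MLP(AvgPool(F)) + MLP(MaxPool(F))) and a spatial gate
   M_s(F) = σ(f⁷ˣ⁷([AvgPool(F); MaxPool(F)])) rescale the feature map
   in sequence. Branch layouts: `vgg16`, `alexnet`, `resnet18`, and a
   CPU-scale `tiny` variant. All layers and their backward passes are
   implemented in the package and validated against finite differences.
3. **Contrastive pair training** —
   L = (1/2N) Σ [ y·d² + (1 − y)·max(margin − d, 0)² ] over image pairs
   (y = 1 same class), Adam, seeded and fully reproducible.
4. **KNN classification** — every training image is embedded into a
   gallery; a query takes the majority label of its k = 2 nearest
   embeddings under Euclidean distance (vote ties fall back to the
   nearest neighbour).
5. **Evaluation harnesses** — accuracy / precision / recall / F1 from
   the confusion tally, an attention ablation (none / channel / spatial
   / both), a k sweep, and a classifier-head comparison
   (KNN vs. SVM, random forest, gradient boosting).

Because clinical scans of this kind are not freely available, the
package includes a synthetic fundus-ultrasound generator (dark field,
bright elliptical fundus, discrete blobs for VO, a continuous arc for
PVD, multiplicative speckle) so the entire pipeline is testable and
reproducible end-to-end. See `vignettes/ocusiam-methods.Rmd` for the
model, design decisions and the generator's limits.

## Worked example

```r
library(ocusiam)

## 1. a reproducible synthetic dataset (no clinical data required)
spec <- synthetic_spec(size = 64, n_per_class = 30, noise = 0, seed = 1)
m  <- generate_dataset(spec, file.path(tempdir(), "demo"))
sp <- stratified_split(m, train_fraction = 2/3, seed = 1)

## 2. preprocess, train the attention siamese branch
pre   <- preprocess_spec(crop = NULL, side = 64)
train <- load_dataset(sp$train, pre)
test  <- load_dataset(sp$test, pre)
net <- build_branch(branch_config("tiny"), seed = 1)
tr  <- train_model(net, train,
                   train_config(learning_rate = 1e-3, epochs = 8, seed = 1),
                   loss_config(margin = 1))
round(tr$history$mean_loss, 4)
#> [1] 0.1873 0.0934 0.0320 0.0045 0.0021 0.0025 0.0019 0.0024

## 3. gallery + KNN classification of the held-out split
gallery <- build_gallery(tr$net, train)
metrics <- evaluate_model(tr$net, gallery, test, k = 2, positive = "PVD")
unlist(metrics[c("accuracy", "precision", "recall", "f1")])
#>  accuracy precision    recall        f1
#>         1         1         1         1
```

The mean contrastive loss collapses from 0.187 to ~0.002 within eight
epochs — positive pairs are pulled to near-zero distance while negative
pairs clear the margin — and the KNN head then classifies the 20
held-out images perfectly. On this noiseless synthetic set the two
classes are separable by construction; the run demonstrates that the
learned embedding recovers that separation.

A command-line front end covering the same pipeline
(`generate`, `train`, `gallery`, `predict`, `evaluate`, `ablate`,
`sweep-k`, `compare-classifiers`) is installed at `inst/cli/ocusiam`;
run it with `--help` for usage.

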