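# atasm

Segmentation of the flexor tendon and synovial sheath in transverse
finger ultrasound, and texture-based detection of trigger finger
(stenosing tenosynovitis), built around an **adaptive texture-based
active shape model**.

In the transverse scan at the A1 pulley the tendon is a bright ellipse
inside a dark synovial-fluid band, with the bright volar plate beneath.
`atasm` fits a 20-landmark point distribution model

    X = X̄ + P b,   −3√λᵢ ≤ bᵢ ≤ 3√λᵢ

to an image by maximizing a weighted energy over the shape parameters
`b` and a similarity pose:

    F = Σₖ Σᵢ wᵢᵏ Fᵢᵏ

with five terms per control point *i*: curvature, a 3×3 area gradient,
a 5×1 line gradient, and Gabor (0°, imaginary) and Laws (E5L5) texture
profile matches. The weights `wᵢᵏ = mean over training of σ·F/F̃` are
learned per term and per landmark from search lines through the true
boundary, so each landmark listens to whichever cue discriminates its
own neighbourhood. Optimization uses a real-coded genetic algorithm
(roulette selection, single-point crossover 0.5, mutation 0.01,
elitism, 10-generation patience) alternated with Powell pose
refinement. The tendon is localized automatically by coarse-to-fine
SAD matching against an averaged intensity template; the sheath is
initialized from the tendon, segmented with sign-flipped gradients,
and completed by the tendon's lower arc (±30° of the downward
vertical) plus two tangent-continuous parabolas. A wavelet + GLCM
texture classifier (divergence-value feature selection, top 20
features, RBF SVM) separates symptomatic from asymptomatic finger
pairs from the 41×21 tendon-centre patch.

A seeded speckle **phantom generator** reproduces the assumed anatomy
(elliptical tendon, synovial band, volar plate, clear/fuzzy bottom
contrast, multiplicative Rayleigh speckle) with known ground truth, so
the whole pipeline trains, runs and is tested without clinical data.

## Worked example

```r
library(atasm)

train <- generate_training_set(10, phantom_spec(), seed = 101)
model <- train_atasm(lapply(train, `[[`, "image"),
                     lapply(train, `[[`, "tendon"),
                     lapply(train, `[[`, "sheath"))

ph  <- generate_phantom(phantom_spec(center_jitter = 6, rng_seed = 777))
res <- segment_tendon(ph$image, model, seed = 42)
cat(sprintf("tendon  DSC %.3f  MAD %.2f px\n",
            contour_dsc(res$contour, ph$tendon_dense),
            contour_mad(res$contour, ph$tendon_dense)))

sres <- segment_sheath(ph$image, res, model, seed = 43)
cat(sprintf("sheath upper MAD %.2f px  group: %s\n",
            contour_mad(sres$sheath_upper, upper_arc(ph$sheath_dense),
                        closed = FALSE),
            sres$group))

cm <- confusion_matrix(tp = 173, fn = 37, fp = 17, tn = 193)
cat(sprintf("accuracy %.2f%%  precision %.2f%%\n",
            classification_accuracy(cm), classification_precision(cm)))
```

prints

```
tendon  DSC 0.983  MAD 0.69 px
sheath upper MAD 0.72 px  group: clear
accuracy 87.14%  precision 91.05%
```

DSC is the Dice overlap of the segmented and true tendon interiors
(1 = perfect, > 0.75 conventionally "similar"); MAD is the symmetric
mean nearest-point distance between the contours in pixels
(0.075 mm/px). The confusion-matrix rates are accuracy
(TP+TN)/total and precision TP/(TP+FP) in percent.

A command-line interface covering simulation, training, segmentation,
evaluation and classification is installed at `inst/cli/atasm`
(subcommands `simulate`, `train`, `segment`, `evaluate`, `classify`;
`--help` for usage). Every run writes a provenance JSON with its
options, seed and package version.

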