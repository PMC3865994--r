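# pombeseg

Robust segmentation of fission-yeast (*Schizosaccharomyces pombe*) cells in
transmitted-illumination (bright-field) microscopy images with focus
gradients and variable contrast.

In bright field, a pombe cell appears as a dark membrane ring around an
interior slightly brighter than the background — until defocus flips the
contrast. A slide tilted against the focal plane produces **both**
polarities in one image, split along the line where the specimen plane
crosses focus. `pombeseg` handles this by:

1. **Region detection** — shading correction; background from Otsu
   thresholding of the gradient image; nuclei from Otsu thresholding of
   registered fluorescence channels; region means μ_N, μ_B.
2. **Focus-gradient correction** — a bilinear plane
   `z(x, y) = a + b·x + c·y` fitted to per-nucleus intensity differences
   `z = mean(nucleus) − μ_B`; pixels with `z < 0` complemented about the
   background mean (`j = 2 μ_B − i`); then a global linear map setting
   μ_N − μ_B to a fixed target Δ.
3. **Pixel classification** — four classes: background, interior
   (`i > μ_N`), membrane (`i` below an Otsu threshold of the sub-histogram
   darker than μ_B) and ambiguous; morphological smoothing; ambiguous
   pixels resolved by iterated Euclidean distance transforms with the
   membrane as a barrier and ties to background.
4. **GVF snakes** — interior components seed closed contours evolved
   under gradient-vector-flow forces from the membrane edge map
   (λ1 = 1, λ2 = 1, α = 0.03, β = 0.2, μ = 0.8).
5. **Contour validation** — RBF-kernel SVMs flag partial and merged
   contours, a classification tree flags background/artifact detections;
   boundary-intersected cells are treated as partial.

A synthetic-scene generator (`generate_scene()`, `scene_preset()`) draws
anti-aliased rod-shaped cells with ground-truth masks, nucleus
fluorescence and an optional contrast-inverting focus plane, so the whole
pipeline is testable — and its validators trainable — without any external
data.

## Worked example

```r
library(pombeseg)

# a validator trained on fixture-derived labels
model <- train_validators(make_training_set(seed = 42), seed = 42)
model
#> <validation_model> trained on 308 samples; CV accuracy: partial 85.8%,
#>   merged 98.0%, artifact (resubstitution) 100.0%

# a 512x512 scene with 28 cells and a focus plane inverting ~1/5 of the frame
scene <- generate_scene(scene_preset("wildtype_gradient", seed = 7))

res <- run_pipeline(scene$field, pipeline_config(), model)
res
#> <pipeline_result> 19 nuclei, 28 contours -> 23 accepted, 5 rejected

res$report$focus$complemented   # the focus gradient was detected and undone
#> TRUE
res$report$focus$plane          # fitted z(x,y): zero line near x = 72
#>       a       b       c
#> -5.3935  0.0751 -0.0146

ev <- evaluate_segmentation(res$label_mask, scene$truth$instance,
        exclude_ids = scene$truth$cells$id[scene$truth$cells$border])
sprintf("recall %.2f, mean Dice %.3f, precision %.2f",
        ev$recall, ev$mean_dice, ev$precision)
#> "recall 0.92, mean Dice 0.925, precision 1.00"

write_results(res$records, res$label_mask, "out/")   # labels.tif, cells.json, features.csv
```

The five rejected contours are the three cells deliberately placed across
the frame border (verdict `partial`) plus contours distorted near the
estimated z = 0 line; removing them is what lifts precision to 1.00.

A command-line front end wrapping these functions ships in
`inst/scripts/pombeseg.R`:

```sh
Rscript inst/scripts/pombeseg.R make-fixture --preset wildtype --seed 7 --out fx/
Rscript inst/scripts/pombeseg.R train-validator --out model.rds --seed 42
Rscript inst/scripts/pombeseg.R segment --trans fx/trans.tif --fluor fx/fluor.tif \
    --model model.rds --out out/
```

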