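# mucorec

Mucosal recovery mapping for endoscopic submucosal dissection (ESD)
specimens of early gastric cancer.

After an ESD resection the specimen is pinned, fixed, photographed and cut
into parallel strips at 2–3 mm intervals; each strip is scanned as a
whole-slide image (WSI). A *mucosal recovery map* projects every section's
microscopic findings — cancerous regions (red), intestinal metaplasia
(blue), normal mucosa (green) — back onto the macroscopic specimen
photograph, linking the endoscopic and pathological views. Building one by
hand takes an expert about an hour per case; `mucorec` implements the
computational pipeline for pathologists and endoscopists who want it in
minutes:

1. **Tiling** — split WSIs and RGB annotation masks into fixed-size patches
   (512 px at 10×), flag blank tiles by HSV saturation, and balance rare
   lesion tiles by stratified random oversampling.
2. **Segmentation** — a U-Net with a ResNet-34 encoder and
   squeeze-and-excitation (SE) channel recalibration on the decoder,
   trained with Adam under the combined loss

   `l = l_Jaccard + l_CE`,
   `l_Jaccard = 1 − (1/N) Σ_i (p_i y_i + s)/(p_i + y_i − p_i y_i + s)`,
   `l_CE = −(1/N) Σ_i Σ_k y_ik log p_ik`,

   where `p` are softmax probabilities and `y` one-hot labels over the
   three mucosa classes. The CNN engine (convolutions, batch norm, pooling,
   reverse-mode autodiff, Adam) is self-contained in the package with
   RcppArmadillo kernels; no deep-learning framework is required.
3. **Stitching** — patch probability maps are reassembled at their original
   offsets (averaged where tiles overlap) into WSI-level class maps, scored
   by MIoU and Dice (`Dice = 2·IoU/(1+IoU)`).
4. **Mapping** — each section is placed on the specimen photo by a rigid
   similarity transform from a layout manifest, refined by normalized
   cross-correlation, and composited into an RGBA overlay with per-class
   areas in mm².

A synthetic histology generator (textured tissue, blob lesions with
pixel-exact masks, whole sectioned specimens with ground-truth layouts)
makes every stage testable without any data download.

## Worked example

Segment a synthetic annotated slide and map a sectioned specimen:

```r
library(mucorec)

## train a reduced SE U-Net on synthetic 128 px patches
train_set <- generate_patch_dataset(200, size = 128, rng_seed = 101)
test_set  <- generate_patch_dataset(50,  size = 128, rng_seed = 202)
net <- build_network(reduced_network_config(128, rng_seed = 42))
fit <- train_network(net, train_set,
                     train_config(epochs = 5, shift_range = c(0, 12),
                                  val_fraction = 0, rng_seed = 11))
tail(fit$log, 1)
#>   epoch mean_loss jaccard_part   ce_part val_miou
#> 5     5 0.5116501    0.1320284 0.3796217       NA

preds <- lapply(test_set, function(s)
  probmap_to_classmap(forward_network(fit$net, s$image)))
miou(do.call(rbind, preds), do.call(rbind, lapply(test_set, `[[`, "cm")))
#> [1] 0.9413883
```

The per-epoch log shows the combined loss and its two parts (their sum is
exact); the final number is the held-out MIoU pooled over all test pixels —
the network separates the three mucosa classes almost completely after five
epochs on purely synthetic texture. (The translation-augmentation range is
scaled from 50 px on 512 px tiles to 12 px on these 128 px patches; see the
methods vignette.)

```r
## end-to-end: sectioned specimen -> recovery map
case <- generate_case(synth_params(slide_size = c(200, 256),
                                   n_lesions = c(2, 2),
                                   lesion_radius_range = c(18, 30),
                                   rng_seed = 303),
                      n_sections = 6)
refined <- lapply(case$sections, function(s)
  list(cm = s$cm,
       layout = refine_layout(s$image, s$layout, case$specimen_photo,
                              mask = s$tissue)))
rmap <- build_recovery_map(refined, case$specimen_photo,
                           microns_per_pixel = case$microns_per_pixel)
rmap
#> <recovery_map> 6 sections; 3014 cancerous px, 2868 metaplasia px; overlap 4089 px
rmap$summary
#>        class area_px area_mm2
#> 1  cancerous    3014    7.535
#> 2 metaplasia    2868    7.170
class_dice(rmap$classmap, case$truth)[2:3]
#>    class1    class2
#> 0.9905645 0.9744125
```

Each section's nominal layout is jittered by up to ±10 px / ±3° in the
photo; the cross-correlation refinement recovers the true placement to
about a pixel, and the composited overlay agrees with the generator's
ground-truth map at Dice ≈ 0.98 per lesion class. `write_image(rmap$composite, ...)`
saves the viewable map.

A command-line wrapper (`inst/cli/mucorec`) exposes the stages as
`simulate | tile | train | predict | stitch | map | eval` subcommands over
YAML configs.

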