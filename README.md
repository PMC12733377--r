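# annotransfer

Semi-automated transfer of pathologist tumor annotations from H&E histology
exports onto fluorescence whole-sample images (e.g. MUSE — microscopy with
ultraviolet surface excitation).

## The problem

Deep-learning models that read fluorescence images of unprocessed tissue
need tumor labels on those images, but pathologists annotate the H&E
sections produced later from the same specimen. FFPE processing stretches,
shrinks and tears the tissue between the two acquisitions, so a rigid
alignment fails, and the modalities differ too much in contrast for
automatic intensity-based registration. `annotransfer` implements the
landmark-based route for researchers building annotated fluorescence
datasets: you pick at least six corresponding points in the two images; the
package does the rest and tells you how well it worked.

## Method at a glance

1. **Registration.** A second-order polynomial transform
   `X = a0 + a1 x + a2 y + a3 x² + a4 xy + a5 y²` (and likewise `Y` with
   coefficients `b`) is fitted per axis by least squares (pivoted QR, unit-
   normalized coordinates, condition-number guard) from the paired
   landmarks — flexible enough for local FFPE deformation, determined by as
   few as six point pairs.
2. **Annotation extraction.** Subtracting the clean H&E export from the
   annotated one recovers the drawn outline, which is morphologically
   closed (disc element) and filled.
3. **Tissue masking.** On the registered fluorescence image: Canny edges →
   gap closing with a disc of size 55 → hole filling → Gaussian smoothing
   (size 63, σ = 53) → threshold 0.1. Dark background drops out.
4. **Refinement and inverse transfer.** The annotation is intersected with
   the eroded tissue mask (removing background the pathologist included on
   purpose), carried back to raw fluorescence space through a role-swapped
   fit, and drawn on the raw image.
5. **Evaluation.** Dice coefficient `2|I1∩I2|/(|I1|+|I2|)`, normalized
   symmetric Hausdorff distance between boundaries, and feature-space
   cosine similarity via a pluggable extractor, plus boxplot-style batch
   summaries.

A phantom generator (`generate_phantom()`) produces paired pseudo-H&E /
pseudo-fluorescence images with a known degree-2 warp, exact landmarks,
ground-truth masks, optional landmark jitter and FFPE-style tissue loss, so
the whole pipeline is testable without slide data.

## Worked example

```r
library(annotransfer)

# a synthetic sample: mild warp, 12 boundary landmarks with 2 px pick error
ph  <- generate_phantom(phantom_params(seed = 7, jitter = 2))
res <- run_pipeline(ph$annotated_he, ph$clean_he, ph$raw_muse,
                    ph$control_points)
res
#> <transfer_result>
#>   fixed frame : 768x768
#>   raw frame   : 768x768
#>   annotation px: 60179 -> refined 60179 -> transferred 58229
#>   registration tissue Dice: 0.996

generics::glance(res$transform)[, c("n_pairs", "rms_px", "condition")]
#>   n_pairs rms_px condition
#> 1      12  1.549   517.437
```

The landmark fit left a 1.5 px RMS residual (the injected pick error) and a
healthy design-matrix condition number; the tissue-overlap Dice of 0.996
is the score you would watch while refining badly picked points. Comparing
the transferred annotation with the phantom's ground truth:

```r
evaluate_transfer(res$transferred_mask, ph$true_tumor_mask_raw,
                  semi_img = res$overlay_image,
                  manual_img = overlay_outline(ph$raw_muse,
                                               boundary_of(ph$true_tumor_mask_raw)),
                  sample_id = "phantom-7")
#>      dsc feature_similarity hausdorff_normalized
#> 1 0.8618             0.9858               0.0441
```

Dice 0.86 says the transferred region overlaps the true tumor well despite
the landmark error; the normalized Hausdorff of 0.044 bounds the worst
boundary deviation at ~4% of the image size. With exact landmarks
(`jitter = 0`) the same pipeline reaches Dice 1.00. Stack such reports
with `dplyr::bind_rows()` and feed them to `summarize_batch()` /
`plot_metric_boxplot()` for per-batch statistics.

A command-line wrapper ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","annotransfer",package="annotransfer"))')" \
  transfer --annotated-he a.png --clean-he c.png --muse m.png \
  --points points.csv --out-dir out --save-intermediates
```

with sibling subcommands `simulate`, `evaluate`, `register`, `extract`,
`mask`.

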