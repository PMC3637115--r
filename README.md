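# fibromorph

Quantitative image analysis of cultured duodenal fibroblasts (FBs):
morphometry of immunofluorescence signals and motility from 72-hour
time-lapse recordings, with group comparison by one-way ANOVA. The
package targets the workflow used to compare FBs from celiac-disease
(CD) biopsies against healthy controls (CTR), where the two populations
differ in the geometry of their collagen and transglutaminase-2 (TG2)
signals ("signet" rounded patterns vs "spindle" elongated ones) and in
how far their nuclei travel in culture.

Because no raw image data are publicly deposited for this kind of study,
the package ships a first-class synthetic-data generator that renders
still scenes of spindle- and signet-shaped cells and time-lapse
sequences of moving nuclei **with full ground truth**, so that every
stage of the pipeline — thresholding, object detection, shape
measurement, tracking, statistics — is validated end to end against
known answers.

## The measurements

For each discrete fluorescent object (ROI) detected after automated
(Otsu) thresholding and minimum-size gating, the pipeline reports:

| quantity | definition | units |
|---|---|---|
| feret diameter | maximum caliper width of the convex hull, F = max over directions of the projected extent | μm |
| orthogonal diameter | hull extent perpendicular to the max-feret axis, F⊥ | μm |
| circularity index | F⊥ / F — 1 for a circle, small for elongated (migration-ready, Y-shaped) cells | — |
| perimeter | length of the sub-pixel (marching-squares) object contour | μm |
| area | pixel count × pixel size² | μm² |
| complexity index | perimeter / area — large for thin, branched outlines | 1/μm |

For time-lapse recordings (10-minute frame cadence over 72 h), nuclei
are detected in the frames sampled every 12 h and linked greedily into
tracks; each complete track yields the total displacement (path length
over the 12-h waypoints, μm) and velocity (displacement / elapsed time,
μm/h). Groups are summarized as mean ± SD and compared with one-way
ANOVA at α = 0.05.

## Worked example

Render three synthetic stills per group — spindle-shaped cells for the
control-like group, signet-shaped for the celiac-like group — and run
the full pipeline:

```r
library(fibromorph)

ctr <- lapply(1:3, function(s) render_scene(scene_truth(
  sample_shape_specs(4, "spindle", seed = s), seed = s)))
cd  <- lapply(4:6, function(s) render_scene(scene_truth(
  sample_shape_specs(4, "signet", seed = s), seed = s)))

cfg <- pipeline_config(pixel_size = 0.5, seed = 1, output_dir = "demo")
res <- run_pipeline(cfg, stills = list(CTR = ctr, CD = cd),
                    reference_areas = rep(900, 12))

subset(res$summaries, parameter %in% c("circularity", "feret_um"))
#>      parameter group  n   mean      sd median    min    max
#> 1     feret_um   CTR 12 42.607  9.1162 40.310 33.015 58.085
#> 2     feret_um    CD 12 43.408 10.3058 41.702 32.685 58.798
#> 9  circularity   CTR 12  0.237  0.0611  0.224  0.150  0.326
#> 10 circularity    CD 12  0.681  0.1005  0.647  0.565  0.890

res$comparisons
#>       parameter        F df1 df2        p significant
#> 1      feret_um   0.0406   1  22 8.42e-01       FALSE
#> 2 orthogonal_um  57.4809   1  22 1.42e-07        TRUE
#> 3  perimeter_um   9.8980   1  22 4.69e-03        TRUE
#> 4      area_um2  27.5992   1  22 2.86e-05        TRUE
#> 5   circularity 171.0471   1  22 7.48e-12        TRUE
#> 6    complexity  83.7228   1  22 5.92e-09        TRUE
```

The two groups were generated with the same feret range, so the feret
comparison is (correctly) non-significant, while circularity — the
parameter that defines the two shape classes — separates them sharply.
The output directory holds the per-object records, group summaries,
comparisons and tracks as CSV, plus a JSON manifest with a content hash
for every file.

For motility, `make_timelapse()` simulates nuclei moving as a
persistent random walk with truncated-normal 12-h step lengths,
`render_frame()` materializes any frame, and `track_nuclei()` runs
detection + linking at the 12-h sampling:

```r
tl <- make_timelapse(motility_spec(5, step_mean = 37, step_sd = 14.7), seed = 1)
summarize_tracks(track_nuclei(tl))
```

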