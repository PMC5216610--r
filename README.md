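# dxr — digital X-ray radiogrammetry of metacarpal cortical bone

Periarticular cortical bone loss is one of the earliest radiographic signs
of rheumatoid arthritis. Radiogrammetry quantifies it from plain hand
radiographs by measuring, at the metacarpal shafts, the outer bone width
*W* and the cortical thickness *T*, and forming cortical indices:

    MCI      = 2 T / W                         (thickness ratio, dimensionless)
    A        = pi T W (1 - T/W)                (cortical area = annulus area)
    MCI_area = A / W^2  = pi (T/W)(1 - T/W)    (area index, max pi/4)
    BHI      = A / (W^1.333 L^0.333)           (size-adjusted, L = bone length)

`dxr` implements the full measurement chain for the two ROI conventions in
use — a **proportional** rule (ROI centred at 44% of the bone length from
the proximal end, length 25% of the bone) and a **narrowest-point** rule
(ROI centred at the minimal shaft width) — together with:

* a synthetic radiograph **phantom generator** with exact ground truth
  (annulus projection model, rounded bone ends, optional caput erosions),
  so every stage is testable without patient data;
* **contour detection** with 32 boundary marks, proximal/distal end
  identification and sub-pixel bone length;
* per-scanline **cortical border localisation**: outer border at the
  maximum intensity gradient, inner border at the maximum radio-opacity,
  with model-based sub-pixel refinement;
* three-way **self-validation** (accept / questionable / reject) of every
  measurement;
* the **clinical statistics** used around these indices: 32-joint ordinal
  (Larsen) damage scores, correlations, a bootstrap test for the
  difference of two dependent correlations, paired agreement, and
  erosion-group contrasts;
* a **synthetic 49-patient study** (`demo_study()`) tying it all together
  deterministically from one seed.

Who this is for: researchers working on automated radiogrammetry or bone
densitometry surrogates who need a transparent, fully testable reference
implementation of the index family and its measurement conventions.

## Worked example

Render a phantom metacarpal (60 mm long, 9 mm wide at the waist, cortical
thickness 1.8 mm) at 300 dpi, detect it, measure the proportional ROI and
validate:

```r
library(dxr)
spec <- phantom_bone_spec(60, 4.5, 4.0, 1.8, proximal_origin_mm = c(10, 6))
img  <- render_phantom(spec, pixel_spacing_mm = 0.0846)
ct   <- detect_bone_contours(img, 1)[[1]]
ct
#> bone contour: 32 marks, L = 59.968 mm, axis (-0.023, 1.000), fit RMS 0.1619 mm
bm <- measure_roi(img, place_roi_bx(ct), ct)
bm
#> bone measurement (bx ROI): T = 1.8101 mm, W = 8.0524 mm, L = 59.968 mm (178/178 profiles valid)
self_validate(bm, ct)
#> self-validation: ACCEPT
aggregate_indices(data.frame(T = bm$T_mean, W = bm$W_mean, L = bm$L),
                  selection = 1)
#> bone indices (1 bones): T 1.8101 mm, W 8.0524 mm, L 59.968 mm
#>   MCI 2T/W 0.4496 | MCI A/W^2 0.5475 (adj 0.4148) | A 35.5 mm^2 | BHI 0.5631
```

The bone was rendered with T = 1.8 mm and a waist width of 8.0 mm; the
measured 1.8101 mm and 8.0524 mm are sub-pixel-accurate recoveries (the
pixel is 0.0846 mm), the ROI contains 178 scanlines, all valid, and the
measurement passes self-validation. `MCI 2T/W` is the thickness-ratio
index; `adj` divides it by the empirical 1.084 constant that aligns
proportional-ROI values with narrowest-point values; `A` and `BHI` follow
the formulas above.

The full synthetic study — 49 patients with severity-coupled cortical
thinning, both ROI modes, bootstrap method comparison:

```r
demo_study(seed = 1, n = 49)
```

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/dxr.R simulate --bones 3 --seed 4 --out out/
Rscript inst/cli/dxr.R measure out/phantom_seed4.tif --mode bx --out out/m.csv
Rscript inst/cli/dxr.R validate out/phantom_seed4.tif   # exit 0/3/4
Rscript inst/cli/dxr.R demo --seed 1 --n 49
```

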