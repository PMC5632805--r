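# phenowell

Automated phenotyping of *Arabidopsis* rosette growth in multi-well culture
plates. High-throughput platforms image hundreds of 6-/12-/24-well plates
from above with a moving RGB camera; `phenowell` turns those images into
per-well green areas and turns the area time series into the growth,
survival and group-comparison statistics such screens report.

The package is aimed at plant scientists running *in vitro* well-plate
bioassays (stress dose-response, chemical or genotype screens) and at
anyone who needs a fully testable implementation of this kind of imaging
pipeline: a ground-truthed synthetic plate generator ships with the package
so every stage can be benchmarked without platform hardware.

## What it computes

**Image pipeline** (per 2500 × 2000 px PNG):

1. Radial lens correction with a single-coefficient division model,
   `r_u = r_d / (1 + k r_d²)`.
2. Plate registration from the tray's blue boundary marks: candidate
   similarity transforms (mm → px) are enumerated over mark–template
   correspondences and ranked by a normalised inverse-residual score.
3. Green segmentation by fixed per-channel HSV cut-offs combined with
   logical AND (hue window ∩ saturation floor ∩ value window).
4. Validation: if any green lies outside the mapped well discs the
   candidate registration is rejected and the next one is tried; images
   where no candidate validates are flagged for manual review.
5. Per-well green pixel counts, numbered column-wise, normalised to a fixed
   reference scale (px/mm) and exported one row per image
   (`filename, date, x, y, area_1..area_n`).

**Statistics** (per plant / treatment / day):

- Relative growth rate `RGR = (ln A₂ − ln A₁)/(t₂ − t₁)`
  (pixel·pixel⁻¹·day⁻¹) and exponential fits `A(t) = A₀ e^{rt}` by
  log-linear least squares, with Pearson's r and the regression F-test on
  the linearised model.
- Group mean ± SE curves, quartile summaries (Q1/median/Q3/min/max/SE),
  survival percentages under an absorbing zero-area death rule, and
  short-interval percentage growth.
- Kruskal–Wallis rank ANOVA across treatments, Conover–Iman post-hoc
  pairwise tests on mean ranks, and compact letter displays ("a", "ab",
  "b", ...) anchored to descending group medians.

## Worked example

A complete synthetic salt-stress experiment — two treatments × three
replicate 24-well plates imaged daily for 9 days — simulated, analyzed and
reported at reduced resolution (width 640 px):

```r
library(phenowell)

design <- experiment_design(c("control", "NaCl150"), replicates = 3,
                            format = "24-well")
sim <- cmd_simulate("salt_demo", design = design,
                    model = salt_stress_model(),
                    times = 0:8, width = 640, seed = 42)

cfg <- segmentation_config(crop_px_per_mm = sim$truth$px_per_mm[1],
                           distortion_k = 5e-9 * (2500 / 640)^2)
rows <- cmd_analyze("salt_demo", "salt_results.csv",
                    layout = "24-well", config = cfg)
#> analyzed 54 images -> salt_results.csv

rep <- cmd_report("salt_results.csv", design, "salt_report")
subset(rep$fits, treatment == "control")
#>   treatment   a0  rate pearson_r  p_value
#> 1   control 16.1 0.403         1 2.52e-15
subset(rep$survival, time == 8)
#>    treatment time survival_pct
#> 9    control    8        100.0
#> 18   NaCl150    8         65.3
subset(rep$letters, time == 5)
#>    time treatment median   H  p_value letters
#> 11    5   control  123.0 107 3.79e-25       a
#> 12    5   NaCl150   21.5 107 3.79e-25       b
```

The control group grows exponentially at the simulated rate
(fitted r = 0.403 day⁻¹ vs 0.4 simulated; Pearson's r = 1 on the group
mean), 150 mM NaCl kills about a third of the plants by day 8, and by day 5
the two treatments separate into distinct letter groups (Kruskal–Wallis
H = 107, p < 10⁻²⁴; areas here are in reduced-resolution pixels). The same
workflow is available from the shell via `inst/scripts/phenowell`
(`simulate`, `analyze`, `report` subcommands).

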