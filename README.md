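# fracmap3d

Three-dimensional fracture mapping of AO/OTA 33A and 33C distal femoral
fractures: from labeled CT segmentations to template-registered fracture-line
and comminution heat maps, fragment morphometrics, and the cohort statistics
used to compare the two fracture classes.

Fracture mapping asks *where* a class of fractures tends to run. Per case,
the segmented fragments are virtually reduced, the model is mirrored if
right-sided and registered to a single reference femur (the *template*,
439 mm long, 82 mm across the condyles) under a 5 mm maximum-surface-distance
quality gate. The curves where fragment interfaces meet the outer cortex
(fracture lines) and the cortical footprint of small fragments (the
comminution zone, defined as fragments **< 1 cm³**) are projected onto the
template, and per-vertex frequencies across the cohort

&nbsp;&nbsp;&nbsp;&nbsp;*f<sub>v</sub> = 100 · c<sub>v</sub> / n* &nbsp;[%]

are rendered as heat maps (dark blue → dark red for lines, white → black for
comminution). Quantitative comparisons between 33A and 33C use the standard
normality/variance decision tree (Shapiro–Wilk → Levene → pooled/Welch t,
else Mann–Whitney U) and the chi-square/Fisher rule (Fisher's exact when
more than 20% of cells have expected frequency < 5).

Patient CT data for this kind of study is typically not shareable, so the
package ships a stylized distal-femur phantom and a seeded fracture
simulator (33A oblique supracondylar patterns, 33C "Y"-shaped patterns with
an intercondylar split, controllable comminution) with exact ground truth —
fragment volumes, fracture-line points, footprints and displacements — so
every pipeline stage is validated end to end.

## Worked example

Simulate a small cohort, build the heat maps, and compare the classes:

```r
library(fracmap3d)

cfg <- pipeline_config(out_dir = "fm_demo", n_33A = 8, n_33C = 5,
                       seed = 42, voxel_spacing = 2)
cmd_simulate(cfg)              # volumes, ground truth, cohort.csv, template.ply
res <- cmd_map(cfg)            # 6 heat maps (all/33A/33C x line/comminution) + QC
print(res$maps$all_line)
#> frequency_map (line): 17416 vertices, n = 13, max frequency 76.9%

measure_zone_extent(res$maps$all_line, threshold = 30, sector = "medial")
#> heat zone (medial, > 30%): -1.0-85.0 mm above the joint line, height 86.0 mm (473 vertices)

rep <- cmd_stats(cfg)
print.data.frame(rep[, c("variable", "test", "p_value", "significant")], digits = 3)
#>                  variable         test p_value significant
#> 1                     age     pooled-t  0.1062       FALSE
#> 2                  height mann-whitney  0.2396       FALSE
#> ...
#> 5             n_fragments      welch-t  0.0886       FALSE
#> 10              mechanism fisher-exact  0.5960       FALSE
```

Every case passes the 5 mm gate here (`res$qc`), the maps land in
`fm_demo/map_*.ply` (per-vertex `frequency` scalar plus RGB; CSV companions
alongside), and `fm_demo/zones.csv` holds the measured heat-zone extents.
The map object reports, e.g., that the hottest template vertex is involved
in 76.9% (10/13) of cases. With the cohort at the published size
(53 + 33A / 21 + 33C, `pipeline_config()` defaults) the same three
morphometric variables that separate the classes in the published cohort —
fragment count, comminuted fragment count, mean comminuted fragment
volume — are the ones the simulator plants as class differences.

The statistics layer also works directly from printed summary tables, which
is how published values can be re-tested without raw data:

```r
compare_categorical(matrix(c(25, 28, 15, 6), 2), variable = "sex")$p_value
#> [1] 0.05904895
t_from_summary(0.14, 0.22, 53, 0.27, 0.24, 21, "pooled")$p_value
#> [1] 0.02862603
```

A thin command-line wrapper is provided for shell use:

```sh
Rscript scripts/fracmap3d.R report --out fm_demo --seed 42
```

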