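# spherostain

Quantification of immunofluorescence staining in multicellular spheroids
embedded in thick hydrogel matrices.

## The problem

Spheroids grown in 3-D hydrogel culture (collagen, basement-membrane
matrix) are stained whole-mount: antibodies must diffuse through hundreds
of micrometers of gel and then into a densely packed cell aggregate. Two
questions dominate the analysis of such experiments:

1. **How deep did the stain get?** On a confocal center slice, a stain that
   has not fully penetrated forms a bright rim with a dark core. The
   standard readout is the *half-maximum radial penetration depth*: radial
   line profiles are cast from the spheroid perimeter toward its center,
   and the depth at which the signal first falls to half the mean perimeter
   intensity is recorded per line and averaged. Normalizing by the spheroid
   radius gives a *fractional depth* in [0, 1], where 1 is complete
   penetration. Regressing depth (or fractional depth) on staining time
   yields the time to complete penetration.

2. **How strong is the signal relative to background?** With a per-channel
   threshold fixed across the whole image set, two statistics are computed
   per spheroid and channel: the background-subtracted **mean intensity**
   (mean of positive pixels minus mean of the sub-threshold "inverse"
   region; negative values mean the background outstains the spheroid) and
   the **total normalized intensity**

   TNI = (Σ positive intensity − mean background × N_positive) / spheroid area,

   which accommodates punctate and heterogeneous stains. Conditions are
   compared with a variance-gated two-sample test: an F-test of variance
   equality decides between Student's and Welch's t-test at α = 0.05.

The package implements this pipeline end to end — segmentation,
background estimation, intensity statistics, radial profiling, half-max
front detection, time-course regression, group comparison — plus a
structured encoding of the staining-protocol schedules (microwave-assisted,
benchtop, and longform benchtop variants) for total processing-time
accounting, and a synthetic confocal image generator with known staining
fronts so everything is testable without microscope data.

It is written tidyverse-style: results are tibbles, fitted objects have
`tidy()`/`glance()` methods, and result types have `autoplot()` methods.

## Worked example

Simulate one ~200-µm spheroid stained for 60 min (staining front advancing
at 0.91 µm/min), then measure it blind:

```r
library(spherostain)

params <- sim_params_mcf10a(staining_time = 60, field_size = 512, seed = 42)
sim    <- simulate_spheroid(params, id = "demo")

thresholds <- determine_thresholds(list(sim$image), mode = "auto")
seg        <- segment_spheroid(sim$image, thresholds)
seg
#> <segmentation_result> center (128.2, 128.1) um, area 118788 px (29697 um2), eq. diameter 194.5 um
#>   thresholds: dapi=4472.4, lamin=2377.5, gm130=546.5, bcatenin=2734.5

pen <- measure_penetration(sim$image, "bcatenin",
                           center = seg$center,
                           radius = seg$equivalent_diameter_um / 2)
dplyr::select(pen, channel, rim_mean, mean_depth_um, sd_depth_um,
              fractional_depth, complete)
#> # A tibble: 1 x 6
#>   channel  rim_mean mean_depth_um sd_depth_um fractional_depth complete
#>   <chr>       <dbl>         <dbl>       <dbl>            <dbl> <lgl>
#> 1 bcatenin    1651.          51.6       0.536            0.531 FALSE

true_front_depth(params)
#> [1] 54.6
```

The measured mean depth (51.6 µm from the perimeter the pipeline itself
segmented) tracks the generator's true front (54.6 µm from the ideal
surface; the ~3 µm offset is the conservative bias of the nuclear-mask
perimeter). `run_pipeline()` does all of the above for a whole image set,
with one threshold per channel across the set, and adds the time-course
regression and the variance-gated group comparison when staining times or
condition labels are supplied.

Protocol time accounting reproduces the workflow bookkeeping directly from
the schedule tables:

```r
s <- builtin_schedules()
total_duration(s$microwave_mcf7_longform_comparison)
#> $minutes
#> [1] 186
#> $hours
#> [1] 3.1
compare_schedules(s$microwave_mcf7_longform_comparison,
                  s$longform_benchtop_mcf7, digits = 1)
#> [1] 7
```

A thin command-line wrapper with `simulate`, `quantify`, `penetration`,
`timecourse`, `compare` and `protocol-time` subcommands is installed at
`inst/cli/spherostain`.

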