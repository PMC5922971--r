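# tactcode

Coincidence coding by tactile afferent subfields, and event analysis of
tactile pointer-alignment trials.

## The scientific problem

Human fingertips discriminate the orientation of touched edges far more
finely than the ~1 mm spacing of first-order tactile neurons suggests.  One
candidate explanation rests on a generally overlooked feature of the
periphery: each first-order neuron branches and innervates many
mechanoreceptive transduction sites, giving it a receptive field (RF) with
multiple highly sensitive zones ("subfields").  Because RFs overlap heavily,
subfields of different neurons are intermingled, and an edge at two slightly
different orientations excites two slightly different *subsets* of neurons —
a coincidence code carried by which neurons fire together, not by firing
rates.

`tactcode` implements, for computational neuroscientists and
psychophysicists:

1. **A population model of this code.**  A virtual 2 x 2 cm skin patch is
   innervated by units at ~1 mm mean 6-nearest-neighbour spacing with
   log-normal RF sizes (log10 area: mean 1, SD 0.45).  Each unit `i` with
   receptor elements `E_i,1..E_i,n` is binary:

   `A(U_i) = 1  iff  A(E_i,1) | ... | A(E_i,n) = 1`,
   `A(E_i,n) = 1  iff  d(edge, E_i,n) < r`,

   with `r = 125 um` for subfield elements (2-64 per unit, first two
   antipodal on the RF boundary) or `r = RF radius` for the uniform-field
   control (one plate-like element per unit).  An edge centered on the patch
   rotates in 0.5 deg steps; the discrimination threshold is the first
   rotation where the Hamming distance between activation vectors reaches
   `0.05 * N_c`, `N_c` being the pool of units contactable by any rotation
   of that edge.

2. **A trial-analysis pipeline** for 1 kHz force / dial-orientation traces
   of a pointer-alignment task (rotate an unseen dial to a target using only
   the touched edge): touch detection (backward search from a 0.2 N crossing
   to baseline + 0.01 N), force-plateau detection (8.7 Hz-filtered force
   rate, 50-350 ms peak window, 10%-of-peak rule), rotation velocity (17 Hz
   symmetric triangular filter, +/-1-sample derivative), sub-movement
   segmentation (minima of 2.1 Hz high-passed speed), alignment-error and
   direction measures, and participant-median summaries with a 75%-correct
   edge-length threshold.

3. **A synthetic trial generator** emulating the task's published structure
   (force ramp to a ~1.64 N plateau, onset ~0.20 s after touch, minimum-jerk
   rotations, 44% sub-movements, online shutter rule: speed < 10 deg/s for
   200 ms) with exact ground truth for parameter-recovery testing.

## Worked example

```r
library(tactcode)

res <- run_paired_experiment(lengths = c(1, 2, 4, 8, Inf),
                             repetitions = 100, seed = 101)
res
#> <experiment_result> 100 paired fingertips, lengths: 1, 2, 4, 8, Inf
#>     variant length   n n_none  mean     sd ci_low ci_high
#> 1  subfield      1 100      0  5.46  5.303   4.42    6.49
#> 2  subfield      2 100      0  4.18  2.954   3.61    4.76
#> 3  subfield      4 100      0  2.35  1.294   2.10    2.61
#> 4  subfield      8 100      0  1.87  0.646   1.74    2.00
#> 5  subfield    Inf 100      0  2.50  0.900   2.32    2.67
#> 6   uniform      1 100      0 23.65 18.607  20.00   27.30
#> 7   uniform      2 100      0 12.12  8.558  10.44   13.79
#> 8   uniform      4 100      0  7.01  3.664   6.30    7.73
#> 9   uniform      8 100      0  5.84  2.181   5.42    6.27
#> 10  uniform    Inf 100      0  6.15  1.564   5.84    6.46
#> paired uniform - subfield differences:
#>   length   n mean_diff sd_diff
#> 1      1 100     18.20   19.49
#> 2      2 100      7.93    9.16
#> 3      4 100      4.66    3.81
#> 4      8 100      3.98    2.20
#> 5    Inf 100      3.65    1.42
```

Each row is the mean discrimination threshold (degrees) over 100 virtual
fingertips.  The subfield model outperforms the uniform-field control at
every edge length, and its advantage grows as the edge shortens (3.65 deg
for the 44 mm "infinite" edge vs 18.2 deg at 1 mm) — short edges engage few
subfields, so heterogeneous fields matter most exactly where the task is
hardest.  `n_none` counts fingertips whose activation never changed by the
criterion (reported, never averaged in).

The behavioral arm closes the loop between generator and pipeline:

```r
cfg <- generator_config(seed = 1)      # 10 participants x 648 trials
ds  <- generate_dataset(cfg)
meas <- analyze_dataset(ds$trials)
summarize_dataset(meas)
#> <task_summary>
#>   edge_length n_participants sem_abs_error sem_p_correct mean_abs_error p_correct
#> 1           0             10        0.7361      0.012688          20.15     0.482
#> 2           1             10        0.7975      0.014725          17.37     0.551
#> 3           2             10        0.6660      0.019702          10.43     0.753
#> 4           4             10        0.2156      0.010885           5.34     0.917
#> 5           8             10        0.1792      0.005091           3.78     0.966
#> 6         Inf             10        0.0974      0.000926           2.80     0.999
#> 75% direction threshold: 1.99 mm; 52 trial(s) excluded
```

The analyzed medians and direction proportions recover the configured
per-length targets, and the 75%-correct threshold lands at the configured
2 mm.  `recovery_report()` compares detected events against ground truth;
on noiseless traces touch, onset and end are recovered within a few
milliseconds and the plateau force within half a percent.

A thin CLI over the same functions lives at `inst/cli/tactcode-cli.R`
(`simulate`, `gen-trials`, `analyze`).

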