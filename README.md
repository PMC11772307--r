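# turtlehr

Heart rate of sea turtles from animal-borne ECG and accelerometer
loggers.

Non-invasive ECG of hard-shelled sea turtles — electrodes on the shell
surface rather than implanted — yields R waves about one tenth the
amplitude of conventional recordings, contaminated by baseline drift and
by muscle (EMG) artifacts concentrated in the minutes when the animal
swims, at heart rates of only 5–20 beats min⁻¹. `turtlehr` implements
the full analysis chain for such deployments, for physiologists and
biologging researchers:

1. zero-phase Butterworth band-pass filtering of the ECG (default
   5–30 Hz);
2. R-wave detection by adaptive windowed-quantile threshold with a
   refractory period (default 1 s);
3. three-level signal-quality grading — *undetectable* (< 30% of the
   record detectable), *unclear* (30–70%), *clear* (> 70%);
4. behaviour classification from the per-minute SD of longitudinal
   acceleration: SD < 0.5 m s⁻² is resting, otherwise moving; runs of
   ≥ 2 min form phases;
5. exclusion of the first 12 h after handling;
6. phase-conditioned heart rate: HR = R-wave count / phase duration,
   with grand means ± SD per status;
7. electrode-placement evaluation tables (counts and percentages per
   placement and grade).

Because no real deployments are publicly available, the package also
ships a synthetic deployment generator with exact ground truth (true
R-wave times, true minute statuses) that emulates the statistical
structure the pipeline assumes; every stage is tested against it.

## Worked example

```r
library(turtlehr)

# a 6-h synthetic deployment at the default study conditions:
# resting 8.6 / moving 12.2 beats min-1, default noise
dep <- generate_deployment(behavior_model(duration_min = 360), seed = 42)
res <- run_pipeline(dep$record, run_config(exclude_hours = 0))
res
#> Heart-rate analysis: turtle SYN01, placement C
#>   ECG quality: clear (detectable 100.0% of record)
#>   3610 R waves, 29 phases analyzed (29 before the 0-h exclusion)
#> Heart-rate summary (pooled pooling):
#>   resting    8.6 +/-  0.2 beats min-1  (n = 15 phases)
#>   moving    12.2 +/-  0.1 beats min-1  (n = 14 phases)

coef(res)
#>   resting    moving
#>  8.645234 12.242368
```

The printed grand means are the unweighted averages of per-phase heart
rates by status; they recover the generator's configured rates because
the detector finds essentially every rendered beat and the
accelerometer classification reproduces the true minute statuses.
`plot(res)` draws the per-minute activity trace with the 0.5 m s⁻²
threshold, the per-phase heart rates, and the per-window detectability
flags. `write_pipeline_result(res, dir)` emits the phase table, the
summary, the R-wave times and the fully resolved configuration as plain
text.

Placement evaluations are summarized from a table of per-animal grades:

```r
evals <- data.frame(turtle_id = c("g1", "g1", "g2"),
                    placement = c("A", "C", "C"),
                    grade = c("unclear", "clear", "clear"))
summarize_placements(evals)
cross_position_improvement(evals, n_total = 2)
```

A thin command-line wrapper with `simulate` / `process` / `summarize`
subcommands is installed at `inst/scripts/turtlehr`.

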