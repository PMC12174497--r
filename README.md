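# prehension

Analysis pipeline for precision-grip object-lifting experiments that probe
anticipatory motor control — specifically, how *repetition* of a practised
lift interferes with the very next lift after the task context switches
(anterograde interference).

The experimental paradigm: a participant repeatedly lifts a visually
symmetric T-shaped object whose centre of mass (CoM) is concealed on the
left or right side. Lifting it without tilt requires the digits to generate
an anticipatory **compensatory torque** at lift onset that counters the
object's external torque. After a run of 1, 3 or 5 lifts the CoM side is
switched; performance on the first post-switch lift measures how strongly
the repeated, now-wrong motor plan intrudes.

## Who this is for

Motor-control and biomechanics researchers working with instrumented
manipulanda (force/torque transducers per digit plus object kinematics) who
need a tested, end-to-end path from raw multichannel recordings to
group-level repetition-interference statistics — and a physically consistent
synthetic-data generator to validate every stage when raw recordings are
unavailable.

## The core quantities

At lift onset (net lift force reaching the object weight), with digit grip
forces `GF`, lift forces `LF`, and frontal-plane torques `Tx`:

- `GF_mean = (GF_thumb + GF_index) / 2`
- `LF_diff = LF_thumb − LF_index` (positive = thumb-heavy sharing)
- `COP_digit = (Tx_digit − LF_digit · t) / GF_digit` with grip-surface
  depth `t` (8 mm): the digit's centre of pressure on the grip surface
- `COP_diff = COP_thumb − COP_index`
- **`M_Com = LF_diff · d/2 + GF_mean · COP_diff`** with grip width
  `d` (82 mm): the compensatory torque, decomposed exactly into a
  lift-force-partitioning component and a grip-force × digit-placement
  component

Grip–lift coordination is the peak of the lagged Pearson correlation
`r(τ) = cor(GF_rate(t+τ), LF_rate(t))` over the load phase, on a 2.5 ms lag
grid spanning ±100 ms.

Group-level inference uses mixed-design ANOVAs (pre-switch repetition 1 vs 3
and 1 vs 5 as the within factor; familiarity — matched vs unmatched pre/post
trial counts — as the between factor), partial eta squared
`F·df1 / (F·df1 + df2)`, and Bonferroni-corrected pairwise comparisons.

## Worked example

Simulate a small matched-design cohort and run the whole pipeline
(filtering at 5 Hz with a fourth-order zero-phase Butterworth, event
detection, lift-onset metrics, sign normalisation, aggregation):

```r
library(prehension)
res <- run_pipeline(default_config(n_subjects = 4, seed = 7))

subset(res$metrics, phase == "post_switch" & position_in_run == 1)[1:3,
  c("subject", "run_length", "gf_mean", "lf_diff", "cop_diff", "mcom")]
#>   subject run_length gf_mean lf_diff cop_diff  mcom
#> 1       1          5    12.9    1.24     5.93  127.
#> 2       1          3    12.9    1.31     6.25  134.
#> 3       1          1    12.9    1.97     9.38  202.

tapply(res$cells$mcom, res$cells$run_length, mean)
#>        1        3        5
#> 228.8203 196.5203 157.2188

res$pairwise
#>   contrast mean_diff     t    df       p p_bonferroni significant
#> 1   1 vs 3     -32.3 -2.96     3 0.0594       0.119   FALSE
#> 2   1 vs 5     -71.6 -6.26     3 0.00821      0.0164  TRUE
```

The first post-switch compensatory torque falls as the preceding run grows
(229 → 197 → 157 N mm here): the planted anterograde-interference effect,
recovered from the raw simulated waveforms. With this deliberately tiny
4-subject cohort only the strongest (1 vs 5) contrast survives Bonferroni
correction; `run_familiarity_analysis()` runs the full two-cohort
(matched + unmatched) mixed ANOVAs.

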