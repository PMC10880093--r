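# kinemark

Marker-less motion biomarkers from 3D joint-centre trajectories.

Clinical teams increasingly capture patient movement — a squat, a
sit-to-stand — with a single RGB camera and a mesh-recovery front end
instead of a marker-based motion-capture lab. What is missing is the step
from raw joint-centre trajectories to something a clinician can act on.
kinemark fills that gap: it extracts planar joint-angle kinematics,
quantifies movement quality, selects a small set of representative
biomarkers per action, and validates pre/post-intervention change with
standard paired statistics, assembling everything into a reproducible
clinical report.

## Method at a glance

For joint centres *k* (vertex), *h* (proximal) and *a* (distal) projected
into the sagittal or coronal plane, with *m = h − k*, *n = a − k*,
*p = h − a*, the joint angle is

> θ = arccos( (|m|² + |n|² − |p|²) / (2 |m| |n|) )

computed at every frame. Repeats of an action are aggregated frame-wise
into mean/min/max curves (no time normalisation). Per curve, kinemark
computes:

- **σ_m** — the sample SD of the curve gradient (deg/s), and the bounded
  score **smoothness = 1/(1 + σ_m/σ_ref)** ∈ (0, 1], 1 = perfectly smooth;
- **J = ∫|α| dt** — cumulative absolute rotational acceleration, where
  ω = Δθ/Δt and α = Δω/Δt, a measure of movement abruptness.

Per participant and action, a two-component SVD PCA over the frames ×
features matrix (features = mean/min/max of every angle) ranks features by
explained-variance-weighted absolute loadings; a cross-participant
histogram of each participant's top-5 features selects the representative
biomarkers. Their pre/post change is tested with two-tailed paired t-tests
(α = 0.05), Bland–Altman limits of agreement (±1.96 SD with approximate
CIs) and percentage-change summaries.

A synthetic cohort generator (planar forward kinematics with known
ground-truth angle curves, band-limited noise and configurable pre/post
effects) makes every stage testable without patient data.

## Worked example

```r
library(kinemark)

# 20 participants, 2 sessions, 2 actions, 3 repeats each, 30 fps,
# with a smoothness improvement injected at knee and elbow flexion
sim    <- generate_cohort(n_participants = 20, seed = 7)
report <- run_pipeline(sim)
print(report)
```

```
Motion-biomarker clinical report
  20 participants, 240 recordings @ 30 fps
  sit_to_stand: 5 biomarkers selected, 10 significant at alpha = 0.05
    * left_knee_flexion_max [cumulative_acceleration], p = 2.09e-11
    * left_knee_flexion_max [smoothness], p = 8.98e-12
    * left_knee_flexion_mean [cumulative_acceleration], p = 7.74e-11
    ...
```

The per-action tables read like a clinical significance table — one row
per selected biomarker and metric:

```r
summary(report)
```

```
== sit_to_stand ==
               biomarker                  metric       t        p df
   left_knee_flexion_max cumulative_acceleration -13.900 2.09e-11 19
   left_knee_flexion_max              smoothness  14.588 8.98e-12 19
  left_knee_flexion_mean cumulative_acceleration -12.883 7.74e-11 19
 ...
```

Negative *t* for cumulative acceleration and positive *t* for smoothness
both mean the post-intervention movement is smoother and less abrupt —
exactly the injected effect. `plot(report, which = "histogram")` draws the
representative-feature histograms, `which = "bland_altman"` the agreement
plots, `which = "percent_change"` the cohort change box summaries, and
`write_report(report, "report.json")` serialises everything (with the full
configuration snapshot) deterministically.

Trajectories can also come from disk: `read_trajectories()` reads the
canonical long CSV (`frame,joint,x,y,z`), TRC interchange files, or a JSON
cohort manifest written by `write_manifest()`; a small simulated example
recording ships in `inst/extdata/simulated_squat.csv`.

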