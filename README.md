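# scopeflow

Colonoscope movement analysis from video frames: estimates the direction of
scope movement over time (insertion / withdrawal / stop), locates the cecum
— the turning point between the insertion and withdrawal phases of a
colonoscopy — and renders the whole procedure as a color-coded timeline.
Intended for endoscopy-video analysis: computing cecal intubation time,
jumping a reviewer straight to the withdrawal phase, and summarizing scope
handling patterns.

## Method

For frames sampled every 0.5 s, the package:

1. filters non-informative frames (blur, over-dark/bright, streaks) with a
   seven-feature SVM (mean, variance, skewness, GLCM correlation and
   contrast, energy of Laplacian, energy of gradient);
2. computes **Horn–Schunck optical flow** between consecutive frames — the
   minimizer of
   `Σ (Eₓu + Eᵧv + Eₜ)² + α²(|∇u|² + |∇v|²)` — and encodes it as a color
   image (hue = direction, saturation = magnitude);
3. classifies each flow-color image as insertion / withdrawal / stop with a
   small CNN (three 3×3 conv blocks with ReLU and 2×2 max pooling, one
   128-unit FC layer with dropout 0.5, softmax; SGD with momentum, batch
   128, randomized hyperparameter search);
4. encodes the labels as a signal `s(t) ∈ {+1, −1, 0}` and scores every
   insertion→withdrawal transition `c` by the signed graph area
   `A(c) = Σ_{|tᵢ − t_c| ≤ t/2} s(tᵢ)·Δt`; the **cecum estimate is the
   candidate with minimal |A(c)|** (insertion area before and withdrawal
   area after cancel at the true turning point), with window widths
   t ∈ {10, 20, 30} s;
5. renders timelines at 1 s / 10 s / 30 s per square with the cecum marked
   (the SRCV summary report).

A synthetic-data module generates every test input with known ground truth:
textured frame pairs under analytic radial/translational motion, degraded
frames, and direction signals with a known cecum time. See the methods
vignette (`vignettes/scope-motion-analysis.Rmd`) for models, conventions
and design rationale.

## Worked example

Locate the cecum in a noisy synthetic procedure (600 s insertion + 400 s
withdrawal, two short oscillations, 15% stops, 8% label noise):

```r
library(scopeflow)

p <- signal_scenario_params(insertion_duration = 600, withdrawal_duration = 400,
                            oscillation_spec = list(c(120, 6), c(340, 4)),
                            stop_prob = 0.15, label_noise_prob = 0.08, seed = 42)
g <- generate_direction_signal(p)
g$signal
#> <direction_signal n=2000  [0.0, 999.5]s  +1/-1/0 = 942/717/341>

locate_cecum(g$signal, t = 30)
#> <cecum_estimate t=30s  time=599.0s  score=-1.0  candidates=116>
```

Label noise creates 116 insertion→withdrawal candidates, but only the true
turning point has a ±15 s window in which positive and negative area cancel
(score −1.0 value·s ≈ 0); the estimate lands at 599.0 s, within one sample
of the true 600 s. Classification metrics come from a confusion matrix the
same way the reference evaluation tabulates them (rows = predicted,
columns = true):

```r
cm <- read_confusion_csv(system.file("extdata", "table1_confusion.csv",
                                     package = "scopeflow"))
compute_metrics(cm)$per_class
#>        class recall precision    f1
#> 1  insertion  0.958     0.976 0.967
#> 2 withdrawal  0.946     0.970 0.958
#> 3       stop  0.967     0.918 0.942
# overall accuracy: 95.6%
```

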