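---
title: "emgfuse: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emgfuse: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the signal models, the classifiers and their assumptions, what the
synthetic data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite does not itself compute.

## 1. Setting

Eight surface-EMG channels are recorded around the forearm at 200 Hz
together with a 6-axis IMU at 50 Hz while a subject holds one of seven
hand gestures for 5 s, with 3 s rest on either side, ten times in each of
four arm positions. The task is *user-independent* classification: models
are fitted on a pool of subjects and evaluated on held-out subjects,
optionally after a very small calibration (two repetitions per gesture
for the adaptive LS-SVM; a single wrist-flexion repetition for the
bilinear model; nothing for the pooled MLP). All cross-validation in the
package is subject-wise; windows of one subject never appear on both
sides of a fold boundary, and normalization statistics are fitted on
training folds only.

## 2. Signal conditioning

EMG is demeaned, notch-filtered at 60 Hz and high-passed at 20 Hz
(4th-order Butterworth); IMU axes are band-passed 0.2–15 Hz (4th-order
Butterworth) and upsampled to the 200 Hz grid with a cubic spline that
reproduces the original samples exactly.

Open choices and how they were resolved:

* **Causality.** The protocol does not fix causal versus zero-phase filtering;
  the package filters zero-phase (forward–backward with odd-reflection
  padding and steady-state initial conditions). Rationale: the pipeline
  is offline, and zero-phase filtering avoids a systematic phase lag in
  detected onset indices. The per-sample IIR core is compiled (Rcpp);
  filter design (bilinear transform of the analog Butterworth prototype)
  is implemented in the package because no filter-design package is
  available in the target environment, and was checked against an
  independent reference implementation during development.
* **Notch bandwidth.** No bandwidth is stated; a standard biquad notch
  with quality factor Q = 30 is used. A high-Q notch has a long
  transient, which is why the attenuation tests measure steady-state
  response away from record edges.
* **Upsampling grid.** The spline output has exactly 4 samples per IMU
  sample, so the two modalities share index arithmetic; the last three
  output samples extrapolate the final spline segment by less than one
  IMU sample period (both streams cover the same nominal duration).

## 3. Activity detection

Each channel passes through the Teager–Kaiser energy operator
$\Psi(x_i) = x_i^2 - x_{i+1}x_{i-1}$, a 50 Hz low-pass, and full-wave
rectification; channels are averaged and smoothed by a forward RMS
window of $W = 60$ samples. The onset threshold is 20% of the mean of
the local maxima exceeding 10% of the global maximum; the offset
threshold is 60% of the onset threshold.

Resolved ambiguities:

* **TKEO endpoints** are set to 0; they always lie in rest periods under
  this protocol.
* **A local maximum** is a sample strictly greater than both neighbours;
  plateaus resolve to their first index.
* **Index alignment.** The RMS window is forward-looking, so output
  index $i$ is attributed to the window start and mapped back to the raw
  timeline without lag compensation, exactly as the smoothing equation
  reads. This makes detected onsets slightly early relative to
  ground truth for sharp bursts — a property, not a bug, and the
  detection-accuracy test accounts for it by asserting a ±0.15 s
  agreement band.
* **Threshold ties** are onset-inclusive (crossing uses ≥ at onset,
  the region extends while the envelope stays ≥ the offset threshold).
* **Multiple regions** mark the trial `ambiguous`, with all candidate
  regions returned. The synthetic pipeline then falls back to planted
  ground truth; on real data a manual-override table would play the role
  of a human reviewer inspecting flagged trials.

## 4. Features

Active segments are cut into 250 ms windows with 50% overlap (50
samples, step 25; only full windows are kept, so a 4.75–4.87 s segment
yields exactly 37). Per EMG channel: MAV, MAV slope, waveform length,
four autoregressive coefficients, zero crossings; per IMU axis: MAV and
waveform length; fusion is plain concatenation (EMG block first).

* **AR estimation** uses the Burg method (standard for short EMG
  windows), order 4, in prediction convention
  $x_i = \sum_k a_k x_{i-k} + e_i$; degenerate (constant) windows yield
  zero coefficients with a warning.
* **MAVS** is the difference between the current and previous window's
  MAV within the same active segment (the dominant convention in the
  time-domain feature literature); the first window gets 0. Whether a
  reference pipeline computes it within or across segments is unstated;
  within-segment was chosen. When windows are subsampled for runtime
  (`window_stride`), MAVS differences are between consecutive *kept*
  windows.
* **ZC deadband** defaults to 0 (none is stated); it is configurable.
* The feature order is frozen in `feature_names()` and pinned by tests.

## 5. Classifiers

### Adaptive LS-SVM

One-vs-all least-squares SVMs: per class, dual weights and bias solve
$[[K + I/\gamma, \mathbf 1],[\mathbf 1^\top, 0]]\,[\alpha; b] = [y; 0]$.
Transfer to a new subject follows the multi-model knowledge-transfer
scheme: prior decision values on the calibration set enter as an offset
term, weighted by a nonnegative per-class vector $\beta$ constrained to
the unit $\ell_2$ ball, and $\beta$ is found by projected subgradient
descent (step $c/\sqrt t$, 300 iterations by default) on the closed-form
leave-one-out squared-hinge loss of the LS-SVM — for this model the
leave-one-out decision values are available analytically from the
inverse of the bordered system, so no refitting is needed inside the
subgradient loop. The adapted machine is the calibration-set LS-SVM
solved against residual targets $y - F\beta$ plus the $\beta$-weighted
prior scores at prediction time.

Open choices: the kernel is RBF with a median-heuristic bandwidth
(linear is available — PCA-reduced inputs are near-linear);
$\gamma = 1$ by default with no tuning loop; multiclass is one-vs-all
with $\beta$ learned per class, which keeps the weights interpretable as
"which prior helps for which gesture". A subtlety pinned by a test:
duplicating every training point is *not* an invariance of the LS-SVM
unless $\gamma$ is halved, since duplication doubles each point's
squared-error weight.

### Bilinear style/content model

Observations of channel $k$ follow $y_k = z^\top W_k\, x$ with a
per-subject style $z \in \mathbb R^2$ and per-motion content
$x \in \mathbb R^3$. The 64 per-window EMG features act as observation
channels (the factorization is classically formulated on raw signal channels; feeding
per-channel feature blocks is this package's documented mapping). The
model is identified only up to the gauge
$(z, x, W) \to (Az, Bx, A^{-\top}WB^{-1})$, so all recovery tests
compare subspaces (principal angles) or canonical correlations, never
raw coordinates.

Fitting is alternating least squares: exact block solves for weights,
contents and styles, hence a nonincreasing residual (asserted on every
run). Two design points matter:

* **Shared contents.** Every subject performs the same protocol, so
  windows correspond across subjects and content vectors are shared
  through a motion index (gesture × position × repetition × window).
  Without this coupling each subject's content coordinate system is
  free, the problem acquires a per-subject gauge, and recovery from the
  stacked matrix is not practically attainable — an early, uncoupled
  implementation stalled far from planted ground truth, which is why the
  coupling is part of the module contract. With a complete
  subject-by-motion grid the (subject·channel) × motion unfolding has
  exact rank $J$, giving a spectral warm start that is exact for
  noise-free data; ALS then refines it. A few seeded restarts guard the
  nonconvexity.
* **Calibration content.** A new subject's style is the least-squares
  solution of the calibration windows against *known* content — taken as
  the mean training content of the wrist-flexion gesture at the matching
  window index. Content for test data is then the per-window
  least-squares projection given the frozen weights and the new style.

Content vectors are Z-standardized per content dimension (equivalently:
each row of the content matrix in its feature-by-sample orientation is
standardized) before training the classifier network — a 50/20 ReLU
network with 20% dropout after each hidden layer, batch normalization
after the first dropout, softmax output, Adam (lr 0.001, decay
$10^{-6}$), 300 epochs, batch 32. In fused mode the per-motion IMU
features averaged across training subjects are appended for training and
the subject's own IMU features at test time. The classifier trains on
per-window rows (sample-count parity with the other methods); whether the
reference pipeline uses per-window or per-segment rows is unstated.

### Classic MLP

A 300/200/100 network with logistic activations and a linear scalar
output, trained by plain SGD (lr 0.2, momentum 0, batch 32) as a
*regression on Z-standardized integer labels* — preserved deliberately,
including the un-standardize → round-half-away-from-zero → clamp-to-1..7
prediction rule, with a softmax variant intentionally out of scope. An
internal 80/20 split provides a validation set. Implementation choices
worth knowing:

* Logistic layers use the ×4 Glorot gain recommended for sigmoid units;
  without it a three-deep logistic stack under MSE barely trains.
* Training tracks validation MSE every 5 epochs, keeps the best-weight
  snapshot, and stops after 20 stale epochs; optionally several seeded
  restarts are trained and the best-validation one kept. Plain SGD on
  this architecture has genuine run-to-run variance, and the validation
  split is the only training-side information used to control it.
* "300 iterations"/epoch counts are interpreted as epochs; batch size 32
  is an assumption (none is stated).

## 6. Evaluation

Features are Z-normalized, scaled to $[-1, 1]$, and PCA-reduced by SVD
to the smallest basis retaining ≥95% variance, applied in exactly that
order. The retained component count is a data-dependent
outcome reported per run, not a fixed setting. Subjects are partitioned
into 5 folds (22 subjects → sizes 5,5,4,4,4). Confusion matrices use
rows = truth, columns = prediction; precision is the column-normalized
diagonal, recall the row-normalized diagonal; zero denominators report
`NaN`. All randomness derives from one root seed through a documented
integer-mixing function, so whole experiments are reproducible.

## 7. The synthetic cohort: what it is and is not

The study's human data are not public, so the generator *is* the data
contract. Its stated world:

* **EMG** is an amplitude-modulated band-limited (20–95 Hz) Gaussian
  carrier — the standard surface-EMG surrogate — plus baseline noise
  (sd 0.05 in units where active amplitudes are ≈0.25–1), a per-channel
  DC offset, and 60 Hz interference (amplitude 0.1), so each
  preprocessing stage has something to remove. Gesture × channel
  activation templates are distinct bumps over the electrode ring;
  gestures also differ mildly in carrier bandwidth (upper edge stepping
  down 4 Hz per gesture class), the generator's stand-in for the modest
  spectral differences between muscle groups — without it the AR and ZC
  features would be pure noise dimensions.
* **Subject individuality**: log-normal channel gains (sd 0.3),
  activation-template deviations with a per-channel component shared
  across gestures plus a gesture-specific component that vanishes when
  gesture templates are collapsed, and a circular electrode-ring
  rotation of −1/0/+1 channels (the protocol anchors one sensor on an
  anatomical landmark, so large rotations are not realistic).
* **Activity timing**: the active region spans 4.8 s of the 5 s hold
  (so segments yield exactly 37 windows), with 0.4 s raised-cosine
  ramps — a moderate-force rise time; ground-truth onset/offset indices
  are stored with every trial, something the real study lacked.
* **IMU**: gravity direction differs across the four arm positions
  (pairwise >20°); gesture-correlated oscillatory motion with
  gesture-specific amplitude and frequency (6–9.6 Hz, fast enough that a
  250 ms window sees more than one cycle, keeping per-window amplitude
  features phase-stable) plus noise. Note the 0.2 Hz high-pass removes
  the gravity component, so at the *feature* level position information
  is carried only weakly; class information in the IMU is what drives
  the fusion benefit.
* A `separability` knob in $[0,1]$ collapses the gesture-dependent
  structure (EMG templates, carrier band, IMU motion) onto its common
  mean: at 0, classes are statistically identical and classifiers sit at
  chance — the generator's null world.

Not emulated: motor-unit physiology, fatigue, force-level variation,
electrode-skin impedance drift, and position-dependent EMG changes. A
green test on this cohort establishes that the pipeline's machinery is
correct and that its comparative claims (fusion helps; transfer beats
calibration-only) hold in a world with the assumed statistical
structure — not that the absolute accuracies transfer to human data.

## 8. Numerical choices

* Bilinear ALS: relative-residual tolerance $10^{-8}$, 500 iterations
  per start, best of 5 seeded starts (the first is the spectral warm
  start); an absolute floor of $10^{-12}\,\lVert Y\rVert_F^2$ stops
  exactly-fitting runs early.
* Projected subgradient: normalized subgradient steps $c/\sqrt t$ with
  $c = 0.5$, projection = clip negatives then rescale into the unit
  $\ell_2$ ball; the best iterate by leave-one-out loss is returned.
* LS-SVM systems are solved densely; a singular system raises an error
  suggesting stronger regularization rather than silently pseudo-inverting.
* Experiment-scale knobs (`window_stride`, row caps for prior training
  and calibration, ALS/epoch budgets) subsample deterministically from
  the root seed; they exist so paired simulation studies fit a compute
  budget and are reported with results. Acceptance experiments reduce
  cohort sizes and training budgets, never assertion thresholds.

## 9. Known limitations

* The bilinear path requires the subject-by-motion grid to align across
  subjects; with detector-derived segments of varying window counts the
  motion index falls back to incomplete-grid updates, and with no
  motion correspondence at all, style/content separation is only weakly
  identified.
* The classic MLP's label-regression formulation makes errors between
  adjacent label codes cheap regardless of gesture similarity; it is
  kept for fidelity, not because it is a good design.
* The adaptive LS-SVM stores calibration kernels densely; very large
  calibration sets should be subsampled (the experiment runner caps them).
* Detected offsets inherit the same forward-window convention as onsets;
  no lag compensation is applied anywhere.
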