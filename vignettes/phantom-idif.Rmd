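---
title: "Simulating and comparing image-derived input functions for dynamic brain PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and comparing image-derived input functions for dynamic brain PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petidif)
```

## The problem

Quantitative brain PET with reversibly binding radioligands estimates the
total distribution volume $V_T$ of a target region from the tissue
time-activity curve (TAC) and the *input function* — the concentration of
unchanged (parent) radioligand in arterial plasma. The reference input
function requires arterial catheterization. Image-derived input functions
(IDIFs) instead read the blood signal from the internal carotid arteries in
the dynamic image itself, but carotids are small (3–8 mm) relative to
scanner resolution, so the measured signal is attenuated by partial-volume
loss and contaminated by spill-in from surrounding tissue.

`petidif` provides (i) a synthetic world — arterial input model, two-tissue
compartment (2TCM) tissue kinetics, a digital head phantom with carotids
imaged through a two-Gaussian point spread function (PSF) with
frame-dependent noise — and (ii) seven published carotid IDIF extraction
methods plus the quantification and figures of merit needed to compare them
against the simulated arterial truth.

## The synthetic world

### Whole-blood model

Whole-blood activity after a bolus follows a Feng-type tri-exponential,
zero until the appearance delay $\tau$:

$$C_{wb}(t) = A_1 (t{-}\tau) e^{-\lambda_1 (t-\tau)}
 + A_2 (e^{-\lambda_2 (t-\tau)} - e^{-\lambda_1 (t-\tau)})
 + A_3 (e^{-\lambda_3 (t-\tau)} - e^{-\lambda_1 (t-\tau)}).$$

Defaults (per template) were fixed once against three stated constraints and
not revisited:

* the peak falls at about 90 s post-injection;
* the decline after the peak is rapid ($\lambda_1 = 3\,\mathrm{min}^{-1}$), as
  in measured bolus curves. This also matters numerically: two of the
  extraction methods fit the post-peak tail with a *nonnegative* mixture of
  three decaying exponentials, which is a completely monotone (convex) family;
  a slow $\lambda_1$ would produce a rounded sampled shoulder that no such
  mixture can trace, a shape real cusp-like bolus curves do not show;
* tail fractions are realistic for a 400–500 MBq ^11^C bolus: whole-blood
  activity at 60 min is 2–3% of the peak.

### Metabolite model

The parent-plasma/whole-blood ratio is a monotone Hill-type curve
$r(t) = 1 - a\,t^h/(t^h + t_{50}^h)$ fit through per-template anchors:
the low-metabolite template keeps $r \approx 0.99$ at 60 min and $0.80$ at
90 min; the high-metabolite template falls from $0.96$ at 4 min to $0.07$
at 90 min. The parent-plasma input is $C_p = C_{wb}\, r(t)$. With these
anchors the parent AUC over 0–90 min is roughly 0.57 of the whole-blood AUC
for the high-metabolite template — the peak carries most of the parent area,
which is the central mechanism the package reproduces.

### Tissue kinetics

Regional TACs solve the 2TCM with blood volume fixed at zero,

$$\dot C_1 = K_1 C_p - (k_2+k_3) C_1 + k_4 C_2,\qquad
  \dot C_2 = k_3 C_1 - k_4 C_2,$$

with $C_T = C_1 + C_2$ and $V_T = K_1/k_2\,(1 + k_3/k_4)$. The solver
convolves the bi-exponential impulse response with the piecewise-linear
input analytically segment by segment, so it is exact for piecewise-linear
inputs; the test suite checks it against an independent Runge–Kutta
integration. Per-region rate constants are realistic for the two tracer
classes (grey-matter $V_T \approx 1.8$–$2$ low-metabolite, $\approx 4$
high-metabolite). Scalp and neck soft tissue are given visible uptake —
real summed PET images show a scalp rim — so spill-in genuinely challenges
the blood-free methods.

### Phantom, PSF and noise

The procedural head phantom (default $96^3$ voxels at 2 mm; 1.22 mm
optional) contains cortical grey sectors, a white-matter core, basal
ganglia, cerebellum, scalp shell, neck soft tissue, air, and two pairs of
vertical carotid cylinders of 8 mm and 5 mm diameter entering below the
brain. Each frame assigns every voxel its label's curve value — sampled at
the frame midpoint (*punctual* mode, the idealized temporal sampling) or
averaged over the frame (clinical-like) — then convolves with the isotropic
stationary kernel

$$K = (1-\rho)\,G(\sigma_1) + \rho\,G(\sigma_2),\qquad
 \sigma_1 = 0.9\ \mathrm{mm},\ \sigma_2 = 2.5\ \mathrm{mm},\ \rho = 0.07,$$

($\rho$ weights the wide component) and adds zero-mean Gaussian noise with
variance $\alpha\,\max(v,0) / (2^{-t/T_{1/2}}\,\Delta t)$, mimicking count
statistics in decay-corrected units (^11^C half-life 20.364 min). The
default $\alpha = 0.02$ gives about 4% relative noise in a carotid voxel at
the peak frame and 25–35% in late-frame tissue voxels, in the range of
high-resolution scanners; it was chosen once as a realism calibration, not
fitted to any outcome. Convolution is separable per Gaussian and exactly
equals convolution with the discretized mixture kernel. Reconstruction
itself is *not* simulated: the kernel is applied in image space. One known
consequence is that recovery never exceeds 1, whereas iterative
PSF-modelling reconstructions overshoot small hot structures by several
percent; measured AUC ratios here cluster tightly around 1 rather than
reproducing overshoot-driven values above 1.

## Extraction methods

All seven methods consume the automatically delineated carotid ROIs
(connected clusters of top-percentile voxels in the summed first two
minutes, within the lower-third axial slab) and, where the original
procedure requires it, a background shell 2–4 voxels away from the carotid
mask.

* **Chen** — models the carotid ROI mean as $RC\,C_{wb} + SP\,C_{surround}$
  and calibrates $(RC, SP)$ by least squares against sampled blood at four
  late times (6/20/60/90 min or 4/20/60/90 min by tracer class). Two
  numerical choices: calibration times snap to the frame containing them
  (the frame is the measurement), and the solve is constrained to
  $SP \ge 0$ — the unconstrained solution can wander along a collinear
  ridge when the surround curve parallels the blood tail.
* **Mourik** — mean of the four hottest pixels per plane (cluster fixed on
  the early summed image), tri-exponential tail fit, then scaled by the
  mean blood/fit ratio at 20/60/90 min. The tail fit minimizes *relative*
  least squares (inputs span two decades) with amplitudes solved by
  nonnegative variable projection.
* **Naganawa** — 6 mm FWHM smoothing, PCA reduction, symmetric FastICA with
  a kurtosis contrast (the bolus component is strongly super-Gaussian on
  the frame axis); the earliest-peaking, most positively skewed component
  is back-projected through its positive spatial weights and scaled by the
  Mourik rule.
* **Su** — Chen's model with the frame-wise hottest carotid voxel as
  pseudo-blood, fit over all frames within a truncation window (defaults
  20/40 min by tracer class; the window can be recalibrated by AUC-ratio
  grid search).
* **Parker** — pseudo-blood from the hottest 5% of carotid voxels per
  frame, with $I_{max} \gets I_{max} I_{mean}/T_{mean}$ on frames where
  the background mean exceeds the carotid mean, then the Chen machinery.
* **Backes** — inverts
  $C_{carotid} = a_v C_{wb} + (1-a_v) k \int_0^t C_{wb}$ on square ROIs by
  forward substitution of the trapezoid-discretized Volterra equation;
  $(a_v, k)$ from a 3-by-4 grid calibrated on the AUC ratio.
* **Croteau** — four hottest pixels over the three adjacent hottest planes,
  tri-exponential fit, divided by a recovery coefficient interpolated from
  a table built by imaging uniform cylinders (3–8 mm in 0.1 mm steps)
  through the same PSF. Partial volume only, no spill-in correction.

Open choices the source descriptions leave unstated were resolved as
follows: Su and Parker estimate $(RC, SP)$ over all early *frames* rather
than four discrete times (both reuse Chen's formula; frames give a
better-conditioned design); Mourik's scaling averages blood/fit rather than
fit/blood (they agree at scale 1); Parker's "hottest 5% of data points" is
read spatially per frame; Chen's least squares is unweighted.

## Quantification and figures of merit

Logan graphical analysis regresses
$\int_0^{t_i} C_T / C_T(t_i)$ on $\int_0^{t_i} C_p / C_T(t_i)$ over frames
with midpoints at or after $t^* = 30$ min (a default; the source start time
is unstated) and reports the slope as $V_T$. On noiseless 2TCM data the
slope converges to $K_1/k_2(1+k_3/k_4)$ from below as $t^*$ grows; with
slowly equilibrating kinetics ($k_4 \approx 0.025\,\mathrm{min}^{-1}$) and a
fat input tail a few percent of negative bias remain at 90 min. Ratio-based
comparisons (image vs blood input on the same TAC) cancel this bias, which
is why the package's figures of merit are ratios.

The unconstrained 2TCM fit is weighted nonlinear least squares (weights
proportional to frame duration), optimized on log-rates from multiple
starts, including a start at the one-tissue corner ($k_3 \to 0$) so nested
data collapses cleanly. Nonconvergence is a flag, not an error: callers
exclude that region, as the clinical procedure does. Input delay is fitted
by a ±30 s grid search (1 s steps) minimizing the early-frame SSE of a
one-tissue fit to the whole-brain curve.

Metabolite correction multiplies a whole-blood curve by $r(t)$ interpolated
*at the beginning of each frame* (the stated convention); both the IDIF and
the arterial reference are corrected identically, so the convention cancels
in ratios. Figures of merit: whole-blood and parent AUC ratios (trapezoid,
0–90 min), grey-matter Logan $V_T$ image/blood ratios, and the scoring rule
(2 points if the mean ratio is within ±5%, 1 within ±5–10%, else 0; the
boundaries are treated as inclusive). "Subjects" in the synthetic setting
are seeded noise replicates.

## What a green test does and does not establish

The generator emulates: realistic curve shapes and kinetics, resolution
blurring by the stated kernel, count-like decay- and duration-dependent
noise, punctual-vs-averaged temporal sampling, and the geometry of small
vessels near warm tissue. It does *not* emulate: iterative reconstruction
(hence no edge overshoot and no reconstruction-coupled noise correlation),
scatter and randoms, attenuation errors, head motion, inter-subject
anatomical and kinetic variability, or blood sampling/assay error (unless
requested via `blood_noise_cv`). Consequently the blood-based methods
recover ratios within a few percent of unity here — consistent with the
qualitative finding that they are the reliable ones — while failure modes
that depend on the excluded factors (notably the historical underperformance
of the recovery-coefficient method, which in this idealized world is handed
its exact diameter and a perfectly matched recovery table) do not fully
reappear. The replicate cohort varies only the noise seed, so method
rankings driven by inter-subject variability compress.

## Numerical choices and degenerate inputs

* Times are minutes everywhere; activities are decay-corrected kBq/mL, so
  decay enters only the noise model.
* Curve extrapolation: linear from $(0,0)$ before the first sample
  (injection starts at zero), hold-last beyond the final sample.
* The 2TCM solver guards the repeated-root case and the $\theta_2 = 0$
  (one-tissue) limit analytically.
* The tri-exponential fitter preserves the measured rise to the peak and
  fits only the tail; nested mono-/bi-exponential tails recover with
  surplus amplitudes at zero.
* Frames are truncated to the analyzed 90 min (27 frames: 6×30 s, 3×60 s,
  2×120 s, 16×300 s); the printed full schedule would end at 95 min.
* Zero tissue activity at an included Logan frame drops that frame with a
  warning; fewer than three usable frames is an error.

## Known limitations

Single anatomical template; carotids are straight vertical cylinders; the
ICA step uses a generic FastICA rather than the specialized EPICA algorithm;
the automated ROI step replaces manual drawing and its operator variability.
The desk-scale default grid (2 mm) doubles the clinical voxel size; the
1.22 mm grid is available at ~4× the cost.
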