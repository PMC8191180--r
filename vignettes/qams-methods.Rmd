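---
title: "Single-marker quantification for a five loop-diuretic HPLC assay: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamskit)
```

## The problem and the method

Routine quality control of multi-component drug preparations by HPLC normally
requires one certified reference standard per analyte (the external-standard
method, ESM). Quantitative analysis of multiple components by a single marker
(QAMS) removes that cost: one well-characterised internal reference substance
is calibrated, and every other analyte is quantified through a
pre-established *relative correction factor* (RCF),

$$\mathrm{RCF}_i \;=\; \frac{A_s / C_s}{A_i / C_i},$$

the ratio of the reference's response factor (peak area per concentration) to
the analyte's. Once the RCF is known, a single run containing the reference at
known concentration $C_s$ yields every other concentration by

$$C_i \;=\; \mathrm{RCF}_i \cdot C_s \cdot \frac{A_i}{A_s}.$$

Because both equations involve only *ratios* of areas, any multiplicative
detector or injection gain cancels — the property that makes QAMS robust in
routine use, and the central invariant this package tests.

qamskit models a concrete assay of this design: five loop diuretics
(torasemide, furosemide, azosemide, etacrynic acid, bumetanide) separated
isocratically on a C18 column, diode-array detection at 278 nm, apices at
4.8, 6.3, 7.6, 9.7 and 18.5 min, with etacrynic acid as the internal
reference. Identification uses a double indicator: the relative retention
time (RRT),

$$\mathrm{RRT} = \frac{t_A - t_0}{t_R - t_0},$$

with $t_0$ the dead-time marker and $t_R$ the reference peak, *and* the
cosine similarity of the peak's UV spectrum (or its first derivative) to a
library spectrum. A peak is identified only when both indicators agree.

## The simulator: what it emulates and what it does not

`render_chromatogram()` builds a diode-array surface as

$$A(t, \lambda) = b_0 + b_1 t
  + \sum_i h_i\, e^{-(t - t_i)^2 / 2\sigma_i^2}\, \frac{S_i(\lambda)}{S_i(\lambda_{det})}
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma_{noise}^2)\ \text{i.i.d.}$$

The apex height $h_i$ is chosen so the *integrated area* of the peak at the
detection wavelength reproduces the analyte's linear response
$a_i C_i + b_i$ exactly; everything downstream therefore measures the
response the assay's calibration table defines. Key defaults of the packaged
`ld5_method()` fixture:

| parameter | default | rationale |
|---|---|---|
| time grid | 0–25 min, 0.005 min steps | the assay completes within 25 min |
| peak sd $\sigma_i$ | $t_i/\sqrt{8000}$ (0.054–0.207 min) | plate-count model for a 150 × 4.6 mm, 5 µm column (~8000 plates) |
| baseline | 2 mAU + 0.05 mAU/min drift | mild, realistic detector drift |
| noise sd | ≈ 68 mAU | calibrated so the reference peak's *area* CV is ≈ 0.5 % at 50 µg/mL, the scale of routine injection repeatability |
| dead-time marker | 1.5 min | an unretained marker must elute before the first peak at 4.8 min |
| wavelengths | 230–360 nm, 1 nm | covers all five absorbance maxima |

Two aspects are deliberately synthetic. First, the five drugs' true UV
spectra are not public; the packaged spectra (`ld5_spectra()`) are mixtures
of 2–3 wavelength Gaussians with the main band at each analyte's reported
wavelength (292/334/326/277/260 nm). They are distinct, realistic
chromophores — good enough to exercise similarity logic, but not measured
data, so the package never asserts specific cross-analyte similarity values;
only structural properties (bounds, symmetry, the first derivative
discriminating more strongly than the original spectra). Second, the
packaged measured RCF table (`ld5_rcf_table()`) carries the assay's reported
values (e.g. furosemide 0.9024 at 334 nm) as data: they were measured at
per-analyte wavelengths and cannot be reconstructed from the 278 nm
responses without the real spectra.

Condition changes (`perturb_method()`) shift retention multiplicatively:
flow rescales all times (marker included) by $1 - \Delta f$; pH, temperature
and organic-modifier changes rescale analyte retention by
$1 + k_{pH}\Delta pH + k_T\Delta T + k_B\Delta B$ with defaults
$k_{pH} = -0.05$ per pH unit, $k_T = -0.005$ per °C and $k_B = -3$ per unit
organic fraction (−3 % retention per percentage point of acetonitrile) —
small monotone shifts of the magnitude the assay's robustness protocol
probes. Detector gain multiplies responses only. Peak shape stays symmetric
Gaussian: exponential tailing is out of scope because every quantity the
package validates depends on areas and apex positions, not shape.

## Signal processing choices

**Baseline.** `estimate_baseline()` uses asymmetrically reweighted penalized
least squares (a Whittaker smoother with a second-difference penalty and
arPLS-style logistic reweighting). This was chosen over simpler
rolling-minimum schemes for two numerical reasons: straight lines span the
penalty's null space, so constant and drifting baselines are recovered
essentially exactly (no edge bias), and the logistic weights stay symmetric
in noise-only regions, so the estimate is *unbiased* under i.i.d. noise —
a lower-envelope estimator would bias every integrated area upward by about
one noise sd times the integration window. Implementation details that
matter: the straight-line component is projected out before solving (it is
unaffected by the penalty, and removing it makes pure-line traces exact to
1e-9); weights are floored at 1e-6 to keep the sparse Cholesky positive
definite; the smoothing length defaults to 1.5 min, wider than the broadest
packaged peak.

**Peak picking.** Local maxima of a lightly smoothed (~0.08 min moving
average) baseline-corrected trace above a threshold (default 10 × the
estimated noise sd, floored at 0.5 % of the tallest signal). Apexes are
refined by 3-point parabolic interpolation. Duplicate apices on one physical
peak — noise wiggles on a broad, flat top — are suppressed by a
valley-prominence rule: a candidate is a separate peak only if the signal
dips by at least max(5 × smoothed-noise sd, 2 % of its height) between it
and every already-accepted peak. Integration bounds sit at the nearer of the
adjacent valley and apex ± 4σ̂, σ̂ estimated from the full width at half
height; ± 4σ̂ captures 99.994 % of a Gaussian area, so bound truncation is
negligible against the 0.1 % area-fidelity requirement. Areas are
trapezoidal on the baseline-corrected signal.

**Resolution** is the base-width convention $R_s = 2\Delta t/(w_1 + w_2)$
with $w$ = (end − start) of the detected integration window.

## Calibration and detection limits

`fit_calibration()` is unweighted ordinary least squares of area on
concentration with Pearson's $r$ — the assay reports simple linear equations
over 2.5–150 µg/mL with no weighting. Back-calculated concentrations outside
the calibrated range are flagged, not rejected (routine QC practice);
non-positive results are errors. The detection limit uses the ICH
noise-over-slope convention LOD = 3.3 σ/slope; each packaged analyte carries
the area-noise sd that reproduces its reported detection limit
(0.08/0.05/0.13/0.25/0.20 µg/mL).

Two RCF estimators are exposed: `compute_rcf()` from a single paired run
(the defining ratio; the default) and `rcf_from_slopes()` as a calibration
slope ratio, which ignores intercepts and warns when an intercept exceeds
2 % of the low-range response. With the packaged responses the intercepts
are 0.1–8 % of the response at 2.5 µg/mL, so the two estimators differ
slightly; the single-run form is what the defining equation states and is
used throughout the validation battery.

## The validation battery and its stochastic models

Every operation in `run_validation()` executes the full pipeline — render,
baseline, detect, integrate, quantify — on simulated injections; nothing is
read off the generator's internal state except expected retention times for
peak-to-analyte assignment. Where a study design needed a choice the assay
protocol does not pin down:

* **Precision**: intraday runs differ by detector noise only; days add a
  multiplicative gain ~ $N(1, 0.01^2)$. The day-level sd was set once so the
  resulting interday RSDs land in the reported 0.4–2.3 % band while intraday
  stays at 0.1–1.5 %.
* **Recovery**: a ~50 µg/mL simulated sample solution spiked at 40/50/60
  µg/mL, each solution injected in triplicate;
  recovery = 100 (found_spiked − found_base)/added per injection.
* **Stability**: injections at 0/1/2/4/6/8 h with optional first-order
  decay; the default (no decay) attributes the reported ≤1.3 % RSDs entirely
  to injection noise.
* **Robustness**: a one-factor-at-a-time grid at the protocol magnitudes
  (pH 3.8/4.0/4.2, flow ±2 %, acetonitrile 34/36/38 %, temperature
  29/30/31 °C), each condition in triplicate with replicate-mean areas —
  RCF RSDs are pooled per analyte over all 12 conditions (the assay reports
  one robustness RSD per analyte), RRT RSDs are reported per factor.
* **Method comparison**: RCFs established from triplicate standard
  injections; each of ≥200 simulated samples is quantified by ESM (own
  curve) and QAMS (reference concentration from its own curve, Eq.-style
  back-calculation for the rest). The agreement statistic is the standard
  deviation of the per-sample percent difference
  100 (QAMS − ESM)/mean — the differences are already relative, and a
  sd/mean ratio of a zero-mean difference would be undefined.
* **Column surrogate**: switching column brands breaks RRT robustness in a
  way within-system condition changes do not. `run_column_surrogate()`
  rescales each analyte's retention by an independent log-normal factor
  (sd 0.15) per "column" and recomputes RRTs analytically — independent
  rescaling can swap elution order, which would confound peak matching, and
  the point of the surrogate is only to show per-analyte RRT RSDs blowing
  far past the 5 % identification criterion while the within-system grid
  stays below ~2 %.

The linearity block uses an area-level generator
(`simulate_calibration_areas()`: packaged response × (1 + 1 % Gaussian))
rather than rendered chromatograms — that is the study design for the
linearity figure, and the area fidelity of the rendering path is verified
separately (rendered noiseless areas match the configured response within
0.006 %).

## Problem sizes and determinism

The shipped experiments use 200 comparison samples, triplicate injections
throughout, a 12-condition robustness grid and a 5001 × 131 rendering grid;
these sizes give stable statistics (the comparison and robustness figures
move by well under their margins across seeds) while a full validation run
completes in well under a minute on one CPU. Every stochastic operation
takes an explicit seed, derives per-injection streams deterministically from
it, and restores the session RNG state afterwards; identical
(method, concentrations, seed) renderings are bit-identical, and report
files re-written under the same seed are byte-identical.

## What passing does and does not show

The simulator realises exactly the assumptions the quantification theory
needs: linear responses, symmetric peaks, additive i.i.d. noise, and
condition shifts that move all retentions together. Passing the battery
therefore demonstrates that the *scheme* — detection, integration,
calibration, RCF transfer, double-indicator identification — is implemented
correctly and is robust under those assumptions. It does not demonstrate
performance on real instruments, where tailing and co-elution distort areas,
spectra carry solvent background, responses drift nonlinearly near
saturation, and matrix effects bias recoveries; the reported wet-lab
accuracy figures for commercial dosage forms depend on real samples and are
deliberately not reproduced here. Known limitations, in one place:
symmetric-Gaussian peaks only; no co-elution deconvolution; single-marker
(not multi-marker) QAMS; RSD-based equivalence only, no formal equivalence
test; synthetic UV spectra; and the packaged measured RCF table is carried
as data rather than derived.
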