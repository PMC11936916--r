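---
title: "Quantifying cerebral blood flow and cerebrovascular reactivity with cvrflow"
author: "cvrflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral blood flow and cerebrovascular reactivity with cvrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrflow)
```

## The measurement problem

Cerebrovascular reactivity (CVR) is the fractional change in cerebral blood
flow (CBF) per unit change in a vasoactive stimulus. Hypercapnic CVR — the
response to a rise in end-tidal CO~2~ (P~ET~CO~2~) — is an established
vascular-health marker; hypoxic CVR — the response to a fall in end-tidal
O~2~ (P~ET~O~2~) or oxygen saturation (SpO~2~) — is smaller, noisier, and in
a subset of people *paradoxical* (CBF falls under hypoxia). cvrflow
implements an analysis chain for a four-phase respiratory protocol
(baseline, isocapnic hypoxia, recovery baseline, hypercapnia) measured with
velocity-encoded (phase-contrast) cine MRI of the two internal carotid and
two vertebral arteries:

1. **Flow quantification** (`vesselFlow`, `totalCbf`, `normalizeCbf`).
   Per cardiac bin, vessel flow is mean ROI velocity times ROI
   cross-sectional area (mask pixel count times pixel area), converted to
   mL/min; the vessel's flow is the unweighted mean over the 8 bins
   (retrospective gating makes bins equal-duration by construction). Total
   CBF is the four-vessel sum; normalised CBF (nCBF, mL/100 g/min) divides
   by brain mass, computed from segmented grey- plus white-matter volume at
   a tissue density of 1.06 g/mL. Before quantification, the background
   phase offset is removed by subtracting the per-bin mean velocity over a
   static-tissue mask (`correctBackgroundPhase`); a least-squares planar
   field is available for spatially varying offsets, but the constant model
   is the default because it is the simplest model consistent with a
   slowly varying offset, and it is exactly idempotent.
2. **Trace alignment** (`alignAcquisition`). Continuous P~ET~CO~2~,
   P~ET~O~2~ and ventilation recordings are averaged over each scan's
   half-open window `[start, start + duration)`. Half-open windows make
   consecutive scans partition time unambiguously; a sample landing exactly
   on a boundary belongs to the later scan. SpO~2~ and heart rate are spot
   readings taken at the sample nearest the scan start, matching how a
   finger-clip monitor is read out at scan onset (window averaging is
   available behind a flag).
3. **Placement reconciliation** (`fitPlacementModel`,
   `reconcileVertebralPlacements`). Slice placement 1 is chosen orthogonal
   to the carotids and can under-estimate vertebral flow; placement 2
   favours the vertebrals. Per vertebral artery, placement-2 steady-state
   flow is regressed on placement-1 flow across the whole group (ordinary
   least squares; one fit per vessel by default, a pooled fit and a
   slope-1 constraint are options). If, at any steady-state timepoint of a
   session, the observed placement-2 flow exceeds the model prediction by
   more than 1.96 residual SDs, that artery's placement-2 values replace
   the placement-1 values at every phase of that session. The residual SD
   is the root mean square error on n − 2 degrees of freedom: a threshold
   must have flow units, so the "SD of the sum-squared errors" can only be
   meaningfully read as the residual SD. The rule is one-sided (placement 2
   is only trusted to reveal *under*-captured flow), and a configurable
   floor (default 1 mL/min) keeps the threshold positive when the fit is
   nearly perfect. Phase physiology always comes from placement-1 scans,
   whose windows are the ones synchronised with the gas record.
4. **CVR computation** (`cvrHypercapnic`, `cvrHypoxicPeto2`,
   `cvrHypoxicSpo2`). With phase values taken from steady-state placement-1
   scans (baseline = initial baseline, never the recovery baseline):

   $$CVR_{HC} = 100\,\frac{CBF_{HC}-CBF_{BL}}{CBF_{BL}\,(P_{ET}CO_{2,HC}-P_{ET}CO_{2,BL})}$$
   $$CVR_{HX,P_{ET}O_2} = -100\,\frac{CBF_{HX}-CBF_{BL}}{CBF_{BL}\,(P_{ET}O_{2,HX}-P_{ET}O_{2,BL})}$$
   $$CVR_{HX,SpO_2} = -100\,\frac{CBF_{HX}-CBF_{BL}}{CBF_{BL}\,(SpO_{2,HX}-SpO_{2,BL})}$$

   The leading minus signs make a CBF rise under a falling stimulus
   positive, so paradoxical responses are negative in every metric.
5. **Concomitant-CO~2~ correction** (`correctForPetco2`). Isocapnic
   targeting during hypoxia is imperfect; any residual P~ET~CO~2~ change
   moves CBF through the subject's own CO~2~ reactivity and masquerades as
   hypoxic reactivity. The session's hypercapnic CVR estimates that
   contribution, which is subtracted from the hypoxic nCBF change before
   re-evaluating the hypoxic CVR equations:
   $\Delta nCBF_{corr} = \Delta nCBF_{HX} - nCBF_{BL}\,(CVR_{HC}/100)\,\Delta P_{ET}CO_{2,HX}$.
   Corrected values are reported alongside, never instead of, uncorrected
   ones, and are unavailable (NA) when the session lacks a hypercapnic
   measurement. At $\Delta P_{ET}CO_2 = 0$ the correction is exactly the
   identity.
6. **Response classification** (`meaningfulChangeThreshold`,
   `classifyResponse`). The median absolute difference between back-to-back
   steady-state scans defines the smallest nCBF change worth calling real;
   changes below it are "minimal", others are classified by sign.
7. **Reliability statistics** (`iccOneway`, `varianceComponents`,
   `wilcoxonSignedRank`, `phaseComparisons`, `pearsonR`, `rSquaredMixed`).
   Described below.

## Statistical components

**One-way intraclass correlation.** Sessions are not distinguishable raters,
so the one-way random-effects model applies: with between- and
within-subject mean squares from rows complete across all sessions,
single-measures ICC(1) = (MSB − MSW)/(MSB + (k−1) MSW) and average-measures
ICC(1,k) = (MSB − MSW)/MSB. Both are reported. The variance components are
the method-of-moments estimates σ²~subject~ = (MSB − MSW)/k₀ (k₀ the
harmonic-adjusted group size, exact for balanced data) and
σ~session~ = √MSW, with negative moment estimates truncated to zero and
flagged. The two ICC variants answer different questions: ICC(1) describes
one session's measurement, ICC(1,k) the k-session average. For reliability
at the reported variance components (subject SD 1.13, session SD 1.37,
mean 4.33 %/mmHg), only the average-measures form is numerically consistent
with the reported overall reliability (1.13²/(1.13² + 1.37²/3) ≈ 0.67,
against 0.41 for single measures); the package therefore treats ICC(1,k) as
the variant that reproduces study-level reliability figures, while exposing
both.

**Exact Wilcoxon signed-rank.** Phase contrasts and steady-state checks are
paired, small-n, and frequently tied, so p-values come from the full
distribution of the positive-rank sum over all 2^n sign assignments
(computed by convolution counting over doubled midranks, valid under ties)
for n ≤ 25, and from a normal approximation with tie and continuity
corrections above. Phase comparisons run 6 variables × 3 contrasts
(hypoxia vs baseline, hypercapnia vs baseline, hypercapnia vs recovery
baseline) = 18 paired tests at a family-wise Bonferroni threshold
0.05/18 ≈ 0.00278.

**Random-intercept R².** The shared variance between hypercapnic and
hypoxic CVR across sessions is estimated from
y = α + βx + b~subject~ + ε, fitted by maximum likelihood profiling the
variance ratio λ = σ²~b~/σ²~ε~ (closed-form GLS at each λ; 1-D optimisation
over log λ), reporting the marginal coefficient of determination
β²Var(x)/(β²Var(x) + σ²~b~ + σ²~ε~). Var(x) is the population (divide-by-n)
variance so that at σ²~b~ = 0 the value collapses *exactly* to the OLS R²;
with the sample variance the collapse would only hold to O(1/n). The
subject-only random intercept is also used for the phase comparisons'
pairing structure; a crossed subject/session random-effects model would be
out of proportion to its role here, since the reliability analysis itself
treats session variation as residual.

## The synthetic cohort generator

Real studies of this design cannot be regenerated at will, so `cvrflow`
ships a seeded generator whose defaults *are* the study conditions the
analysis assumes; they are fixed once and everything downstream is tested
against them.

- **Cohort**: 21 subjects × 3 sessions by default. Baseline physiology per
  subject: nCBF 63 ± 9 mL/100 g/min, P~ET~CO~2~ 41.0 ± 2.6 mmHg,
  P~ET~O~2~ 112.3 ± 8.8 mmHg, SpO~2~ 98 ± 1 %, heart rate 67 ± 8 bpm,
  ventilation 9.2 ± 2.5 L/min, brain volume 1166 ± 110 mL (a 1236 g brain
  at 1.06 g/mL, so 779 mL/min normalises to 63 mL/100 g/min).
- **Stimuli**: achieved hypoxic P~ET~O~2~ 61.6 ± 3.6 mmHg, drawn
  independently of the 55–70 mmHg target band; hypercapnia attains its
  +6 mmHg target on average (±0.8 mmHg between sessions). During hypoxia
  P~ET~CO~2~ drifts by −0.4 ± 0.9 mmHg despite isocapnic targeting — the
  perturbation the correction exists for. SpO~2~ under hypoxia follows a
  linear coupling to P~ET~O~2~ (0.158 %/mmHg, reaching ≈90 % at the default
  stimulus) plus 1.6 % noise; the coupling achieved in vivo is not known
  precisely, so this is an explicit modelling choice.
- **True reactivity**: hypercapnic CVR 4.33 %/mmHg with subject SD 1.13 and
  session SD 1.37; hypoxic CVR 0.10 %/−mmHg with subject SD 0.07 and
  session SD 0.14. A 15 % paradoxical mixture draws negative subject-level
  hypoxic CVR (−|N(0.08, 0.04)|); the remaining subjects draw from the
  positive part of the normal, so `paradoxFraction = 0` guarantees none.
  Because session deviations can flip signs, paradoxical *instances* occur
  in non-paradoxical subjects too, as observed in vivo.
- **Flows**: each scan's nCBF equals the subject's true baseline modulated
  through the session's true reactivities by the gas levels *measured in
  that scan's window of the generated trace*, plus N(0, 2.1) acquisition
  noise, converted to mL/min and split 0.38/0.38/0.12/0.12 across
  ICAs/VAs (a typical physiological distribution; configurable). Using the
  window-measured gas values, rather than the latent plateaus, is what
  makes the pipeline's estimates exactly recoverable at zero noise: the
  estimator and the generator then agree about what the stimulus was. The
  2.1 mL/100 g/min noise SD is fixed by the repeatability calibration
  median|N(0, 2σ²)| = σ√2·Φ⁻¹(0.75) = 2.0.
- **Placement effect**: in 15 % of sessions one vertebral artery's
  placement-1 flows are attenuated by a factor α ~ U(0.70, 1.0)
  (phenomenological: the study design gives no physical projection model).
  Attenuations near 1 are undetectable *in principle* — their deviations sit
  below any threshold the group relationship can support — so exact
  parameter-recovery checks either disable the effect (`zeroNoiseConfig`)
  or use strong attenuation (α ≤ 0.75), which the 1.96-SD rule reliably
  flags and neutralises.
- **Schedule**: a 46-minute session: baseline (scans at placement 2, 1, 1),
  a transition window with three placement-1 scans while gas ramps and
  flow stabilises, steady hypoxia (1, 1, 2), one recovery-baseline scan, a
  transition into hypercapnia, steady hypercapnia (1, 1, 2); all scans 60 s
  on a 1 s trace grid. Transition scans carry the `transition` phase label
  and are excluded from CVR by that label alone. In the generator, flow
  tracks gas instantaneously (the slow CBF response that motivates the
  stabilisation wait is not simulated — transition scans exist to exercise
  the exclusion logic, not to model dynamics).
- **Pulsatility and images**: per-bin flows modulate a raised-cosine
  waveform with peak/mean 1.6 and unit mean (only the cycle mean matters
  downstream). At image fidelity each acquisition renders 4 parabolic-profile
  discs (carotid radius 0.28 cm, vertebral 0.20 cm → 28- and 20-pixel
  diameters at the 0.02 cm default pixel) whose analytic integral equals the
  requested flow, plus a constant background phase offset drawn from
  ±0.5 cm/s and optional voxel noise; center-in-disc pixel masks give
  discretisation errors well under 2 % at these diameters.

What the generator does **not** emulate: k-space/MR physics, velocity
aliasing, motion, gating errors, clock drift between the gas record and the
scanner (alignment is exact by construction), ROI segmentation error, or a
curvilinear hypoxic dose–response (the linear CVR definition is the
analysis target). Passing tests therefore demonstrate the *estimators* are
correct under the stated statistical structure, not that real acquisitions
meet that structure. One deliberate infidelity: the generator lets
hypercapnia attain its +6 mmHg target on average, while the measured
achieved rise in vivo was nearer +5; the internal consistency checks
(phase-summary construction, CVR error propagation) assume the target.

## Numerical and degenerate-input conventions

- Windows with fewer than 2 samples, or outside the trace, are errors; a
  phase without steady acquisitions is *absent*, and downstream CVR for it
  is NA rather than an exception (incomplete sessions are data, not bugs).
- Zero stimulus changes make the corresponding CVR an explicit error in the
  scalar equations and NA in the orchestrated pipeline.
- The substitution threshold floor (1 mL/min) guards the zero-residual
  degenerate fit; forcing `sdFloor = 0` with a perfect fit and a positive
  deviation raises an error pointing at the floor.
- On noise-free data the meaningful-change threshold is 0; every nonzero
  change is then classified by sign.
- Negative variance moment estimates truncate to zero with a warning; ICC
  requires ≥2 complete rows; the Wilcoxon test on all-zero differences is
  an error.
- Full-precision (17 significant digit) CSV and double-precision NIfTI
  serialisation make `readStudy(writeStudy(s))` equal to `s` and the
  written bytes a pure function of the study content (the NIfTI header's
  float32 pixel spacing is the one lossy field, at relative 1e-8).

## Problem sizes used by the checks

The packaged checks run on one CPU in a few minutes: exact recovery on a
noise-free 21 × 3 cohort; reliability recovery over 200 replicate 19 × 3
cohorts (the simulation interval of ICC(1,3) brackets the
variance-component prediction); correction efficacy on 60 sessions at a
fixed seed (at that n the sampling noise floor of a zero correlation is
≈0.1, so single-seed values scatter around it — the fixed seed shows a
typical realisation, and the uncorrected coupling ≈0.35 disappears on
average); threshold calibration on ≥500 back-to-back pairs; error
propagation of the acquisition noise through the hypercapnic ratio
(MAE ≈ 0.5 %/mmHg — the baseline scan's noise enters both the numerator
and the denominator, which analytic propagation must include).

## Limitations

Session-level jitters of baseline physiology (e.g. 0.5 mmHg P~ET~CO~2~) are
fixed constants, not exposed configuration; a truly constant cohort is
therefore not constructible. The variance components fed to the generator
are treated as *true* latent variability, with measurement noise added on
top — to the extent published components already contain measurement noise,
the generated data are slightly noisier than the study they emulate, which
depresses replicate ICCs by a few hundredths. The recovery-baseline phase
has no placement-2 scan, so a flagged vertebral artery keeps its
placement-1 value there (the recovery baseline never enters CVR). Image
fidelity renders one cine per scan and is intended for small cohorts;
flow fidelity is the default for cohort-scale simulation.
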