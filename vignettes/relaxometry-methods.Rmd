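---
title: "Methods: simulation-based neonatal relaxometry at 7 T"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-based neonatal relaxometry at 7 T}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `neorelax`, the choices
made where the published protocol leaves details open, and what the
package's validation does and does not establish. All quantitative
statements below are computed by the test suite
(`tests/testthat/`), the analysis drivers (`analysis/`) or
`scripts/acceptance.R`; none are asserted from memory.

## The measurement chain

The package reproduces a single-slice neonatal relaxometry protocol at 7 T:

* **T1**: inversion-recovery single-shot TSE at eight effective inversion
  times (0.5–5 s plus a no-inversion image), TR 10 s, with an enforced
  recovery rule `TR − Ti + Tshot + Tdelay ≥ 20 s` (Tshot ≈ 0.37 s).
  Magnitude images are fitted voxelwise to
  `S(Ti) = S0 (1 − 2(1−ε) exp(−Ti/T1))`, where ε ("inversion
  inefficiency") absorbs both imperfect adiabatic inversion and the fast
  initial recovery produced by magnetization transfer at ultrahigh field.
  The no-inversion image is the `Ti → ∞` limit of the same model, not
  `Ti = 0`.
* **T2**: a three-shot 2D TSE, echo train length 24, refocusing 180°,
  whose 5th, 13th and 24th echoes form the centres of three k-spaces at
  nominal TE 59/154/283 ms. A voxel's three echo amplitudes are matched
  against a Bloch-simulated dictionary indexed by (T2, T1, B1rel).
* **B1**: dual-TR actual flip-angle imaging (TR 23.5/117.5 ms, nominal
  60°), inverted with the standard short-TR arccos estimator and
  trilinearly resampled from its coarse 3D grid onto the mapping slice.
* **ROI medians** after one-pixel label erosion, and **mixed-effects age
  regression** of the per-tissue medians across a cohort.

## The echo-train simulator

Signals are predicted by evolving an ensemble of isochromats through one
full echo train and integrating transverse magnetization over the voxel:
51 readout × 501 through-slice isochromats covering 1 mm × 4 mm (the
readout axis carries no gradient in this model, so it contributes a pure
multiplicity; it is retained for structural parity and for future
readout-dephasing experiments).

Choices the protocol leaves open, fixed here as follows:

* **RF pulses**: Hamming-windowed sinc, time–bandwidth product 4, 250
  hard-pulse samples, identical nominal slice width for excitation and
  refocusing, refocusing phase 90° from excitation (CPMG). Flip angles
  scale linearly with B1rel.
* **Instantaneous composite rotations**: each shaped pulse is applied as
  the composite of its hard-pulse sub-rotations (with the slice-select
  gradient interleaved, and the standard half-area rephasing lobe after
  excitation), while relaxation acts over the full inter-pulse intervals,
  which preserve the exact echo timing. Relaxation *during* a ~2.6 ms
  pulse is a second-order effect on echo-centre magnitudes; folding it
  into the free intervals is what makes the simulator agree with the
  extended-phase-graph (EPG) formalism to 3×10⁻⁵ relative (measured in
  `test-epg-oracle.R`) and makes the 12 288-atom dictionary build take
  seconds rather than hours.
* **Crushers**: an instantaneous linear phase of 4 cycles across the 4 mm
  simulated extent on each side of every refocusing pulse, plus — because
  practical crushers dephase spins by many cycles *within* each grid
  position — 8 uniformly spread intra-voxel phase offsets per position
  (the strong-crusher limit). The phase-offset ensemble cancels coherence
  pathways with non-zero net crusher count *exactly*; without it they
  cancel only approximately across the discrete profile grid and leave
  percent-level residues at any affordable grid size.
* **Echo timing**: the quoted 11.2 ms echo spacing is inconsistent with
  TEs of 59/154/283 ms at echoes 5/13/24; the TEs are what enter the decay
  model, so the spacing is derived as 283/24 ≈ 11.79 ms and the nominal
  value kept as metadata.

**Grid convergence.** With this gradient model the late echo carries
intra-voxel dephasing oscillations of up to ~120 cycles across the 4 mm
extent. The default 501-point profile grid resolves them: doubling the
grid changes the extracted echoes by ~10⁻⁵ (asserted in `test-bloch.R`).
*Halving* to 251 points under-resolves the 24th echo by ~2.5%, so the
default grid should be treated as the minimum for late-echo work.

## Dictionary, interpolation and matching

The coarse dictionary covers 32 T2 values (10–480 ms), 24 T1 values
(0.5–4 s) and 16 B1rel values (0.2–1.5), trilinearly interpolated to
1 ms / 10 ms / 0.01 steps. The fine dictionary is evaluated lazily — the
full fine grid would hold ~2.2×10⁷ atoms — and matching restricts to the
nearest fine B1 node and the assumed T1, maximizing cosine similarity
(the normalization makes matching invariant to the arbitrary scale of
magnitude images). Grid corners with T1 ≤ T2 would be flagged; the default
axes contain none (minimum T1 500 ms exceeds maximum T2 480 ms).

Two accuracy floors of the method as published are worth knowing:

* **T2-grid quantisation**: estimates live on a 1 ms grid, so at
  T2 = 10–30 ms a single grid step is a 3–10% relative error. Any
  statistic defined as a pointwise maximum over sampled entries saturates
  on this floor; the package therefore reports the *robust* region bound
  (95th percentile of |relative bias|) alongside per-(T1, B1)-cell maxima
  and 95th percentiles in the bias study.
* **B1-axis curvature**: between the 16 coarse B1 nodes (spacing 0.087)
  the late-echo amplitude is visibly curved, so linearly interpolated
  atoms at off-node B1 deviate by several percent on that echo. This sets
  a ~2 ms median floor on T2 recovery for off-node B1, reaching ~3 ms at
  the long-T2 edge of the dictionary (PVFWM, 146 ms). The error is a
  property of the published axes, not of the phantom shortcut: matching
  directly simulated per-voxel signals reproduces it.

**Fixed-T1 bias.** Matching with T1 fixed at 2.6 s is deliberate: the
dictionary is only weakly T1-dependent, and feeding a measured T1 map back
in would inject its noise into T2. The bias study samples fine-grid
entries, re-estimates T2 under the fixed T1 and summarises relative bias;
at desk scale (20 000 samples, reduced-fidelity grid) the robust bound
over 2 s < T1 < 3.5 s and B1rel > 0.5 is ≈ 1.5% (see
`analysis/03_bias_study.R`), and a voxelwise-true-T1 dictionary changes a
phantom T2 map by a median of ≤ 2 ms — which is why the fixed-T1 map is
the default.

## T1 fitting

The magnitude objective `| |model| − data |²` is multimodal near the null
point, so the bound-constrained Levenberg–Marquardt fit (minpack.lm) is
started from T1 ∈ {1, 2.6, 4.5} s × ε ∈ {0.01, 0.2} and keeps the best
optimum (function tolerance 10⁻¹⁰, parameter tolerance 10⁻⁸; an early exit
skips remaining starts once the residual is numerically zero). Voxels with
fewer than four usable images, no no-inversion image, or all-zero signal
are flagged invalid; active bounds are flagged `boundary_active` — note a
signal with *no* inversion contrast is equally well explained by ε → 0.5
or T1 → 0, both boundary solutions. Including ε keeps T1 unbiased even
when inversion is degraded regionally (tested with ε fields up to 0.4).

Registration (same-contrast series) minimises the mean-squared error of
intensity-normalized images over in-plane translation (±10 px) and
rotation (±10°), by a coarse grid search at 4× downsampling followed by
Nelder–Mead refinement at 2× and full resolution; recovered transforms are
reported for QC, and images rejected after visual inspection are dropped
with bookkeeping.

## The synthetic generator

`make_phantom()` builds a 160×160 brain-like slice (0.8 mm pixels)
containing all eight tissues with at least 50 pixels each: a cortical
ribbon around white matter, paired basal ganglia and thalami, a brainstem
column, cerebellar lobes with a midline vermis, and PVFWM caps composited
with priority. Per-tissue T1/T2 come from the generating lines (below) at
the phantom's PMA, with a ±1% within-tissue jitter for realism; the
proton-density-like S0 map, the relative-B1 field (smooth, default range
0.65–1.25, gradient < 0.02/pixel — a plausible transmit-field variation
for a small head in a 7 T head coil) and the ε field (default 0.03–0.12)
are band-limited smooth fields. Noise is Rician (magnitude of complex
Gaussian), calibrated to a reference-image SNR (default 50); optional
per-image rigid jitter emulates inter-acquisition motion. Every simulated
dataset ships its ground truth.

The TSE forward simulation evaluates each tissue on a small local
(T2 ± 1.5%, B1) grid and interpolates per voxel — at reduced isochromat
fidelity this keeps a full exam under a few seconds while agreeing with
per-voxel simulation to well under the matching floor.

**Cohorts.** `make_cohort()` draws 34 subjects over 40 exams (6 second
scans), GA ~ truncated normal (36, 3) on [27.8, 42.2] weeks, PMA ~
truncated normal (39.7, 3.5) on [33.5, 53] weeks with PNA = PMA − GA ≥ 0
enforced; per-tissue values follow the generating line plus a
subject-level intercept and residual noise. The variance components are
not published; the defaults (between-subject/residual SD 50/100 ms for T1
and 3/4 ms for T2) were calibrated once, by pilot simulation, so that
simulated intercept CI half-widths at ~37 usable exams are of the order of
the reference intervals (±40 ms for the white-matter T1 intercept), and
were not revisited. Options emulate the study's data losses: 8 exams
without AFI (no T2), one T2 motion rejection, and 3 pathology-flagged
subjects carried with `excluded` flags (never silently deleted) so the
exclusion logic stays visible in the table.

Generating lines (40-week intercept in ms, slope in ms/week):

| tissue | T1₄₀ | Δ₁ | T2₄₀ | Δ₂ |
|---|---|---|---|---|
| cortical grey matter | 2775 | −12 | 98 | −0.9 |
| white matter | 2933 | −20 | 119 | −1.8 |
| brainstem | 2347 | −11 | 83 | −1.3 |
| cerebellum | 2653 | −43 | 99 | −4.1 |
| cerebellar vermis | 2436 | −30 | 86 | −2.3 |
| basal ganglia | 2486 | −23 | 90 | −2.0 |
| thalamus | 2469 | −23 | 90 | −1.7 |
| PVFWM | 3165 | −24 | 146 | −1.3 |

## Mixed-effects inference

`fit_age_model()` fits `value ~ (PMA − 40) [+ PNA] + (1 | subject)` by
REML. At this design (34 subjects, 6 repeats, intraclass correlation
≈ 0.2) the random-intercept variance is weakly identified: it is estimated
at the zero boundary in roughly a third of simulated cohorts, which
deflates naive standard errors. Calibration simulations (the coverage
property in `test-acceptance.R`; pilot summarised in
`analysis/05_recovery_study.R`) measured ≈ 88% coverage for plain
±1.96·SE Wald intervals and ≈ 94–95% for Kenward–Roger adjusted SEs and
degrees of freedom, so Kenward–Roger is the default (`"wald-normal"`
remains available). p-values test a zero slope; exact noiseless tables
reduce to an OLS fallback flagged `singular`. Per-tissue fits are
independent and unadjusted for multiple testing, matching the per-ROI
regression design.

## Problem sizes used in validation

Dictionary-dependent tests and the acceptance script use a
reduced-fidelity 15 × 101 isochromat grid (the full parameter axes are
kept); simulator-accuracy tests use the full 51 × 501 grid. Bias studies
sample 20 000 entries; recovery studies use 100 cohorts per setting;
coverage uses 1000 table-level replicates (enough to place the Monte-Carlo
error of a ~95% proportion well inside a ±2-point band). Phantom round
trips use the default 160×160 slice noiselessly and 96×96–120×120
elsewhere.

## What passing tests do and do not show

The generator shares the estimators' forward models (Eq. above for IR, the
Bloch simulator for TSE, the ideal-spoiling AFI ratio), so round trips
validate *implementation* and *conditioning*, not model adequacy on real
tissue: magnetization-transfer-driven multi-exponential recovery, B0
off-resonance, diffusion through crushers, through-plane motion, k-space
artefacts (GRAPPA, partial Fourier) and segmentation error are all outside
the simulated physics. The cohort generator assumes linear-in-PMA means,
Gaussian variance components and missingness independent of the outcome.
Conclusions supported by the tests: the fitters invert their own forward
models to stated tolerance; the dictionary machinery reproduces an
independent EPG oracle; the mixed-model pipeline recovers generating lines
without material bias and with calibrated intervals under the stated
design.

## Known limitations

* The acquisition-specific gradient waveform set is not published; the
  crusher/slice-gradient model here is a declared approximation, and
  profile-grid requirements (501 points) follow from it.
* Dictionary T2 at off-node B1 carries the ~2 ms interpolation floor
  described above; late-T2 tissues (PVFWM) sit closer to 3 ms.
* AFI noise propagates steeply through the arccos estimator (≈ 0.03 RMSE
  in B1rel at SNR 50); no spatial smoothing of the B1 map is applied.
* Registration is in-plane rigid only; through-plane motion cannot be
  corrected, only rejected.
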