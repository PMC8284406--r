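---
title: "Quality control for automated solution scattering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for automated solution scattering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsqc)
```

# Scope

When solution scattering samples are mailed in and measured unattended, the
checks a scientist would perform at the instrument have to run as code.
`saxsqc` implements four such components and a synthetic-data generator that
makes all of them testable without beamline data:

1. a **longest-run ("coin toss") similarity statistic** with exact null
   p-values, for deciding whether two 1-D scattering profiles differ only by
   noise;
2. **beam-center verification** from the centro-symmetry of low-angle
   scattering on the 2-D detector image;
3. an **automated buffer-subtraction scaling factor**, replacing the manual
   fine-tuning of the buffer weight after water-peak matching;
4. a **sample-logistics layer**: spreadsheet validation, plate-to-holder
   transfer planning, deck allocation and the holder manifest compiled
   before a collection run.

# The longest-run statistic

Two measurements of the same curve differ only by noise, so at each point of
a common q grid either curve is equally likely to be the higher one — a fair
coin toss. The comparison is reduced to a sign sequence (+1 where the first
curve is higher, −1 where the second is; exact ties are dropped because they
carry no direction), and the sequence is summarized by its *patches*:
maximal runs of identical sign. Systematic disagreement between the curves
shows up as an implausibly long patch.

`longest_run_pvalue(n, l)` evaluates `P(longest run >= l)` over all `2^n`
equally likely ±1 sequences exactly, by dynamic programming over the current
run length (a vector of probabilities `P(current run = k, no run >= l yet)`
updated one toss at a time). No asymptotic approximation is involved; the
profiles compared here have at most a few hundred points, so the O(n·l)
recursion is instantaneous, and the suite checks it against exhaustive
enumeration of all sequences up to n = 16.

Two null variants exist: runs of *either* symbol (the default, matching a
patch histogram built from both 1 and −1) and runs of a designated symbol
(`symbol = "heads"`). The two differ: a run of either symbol of length l in
n tosses is as frequent as a heads-run of length l in n − 1 tosses. Which
one a beamline uses is a convention choice; both are provided, with
either-symbol as default because the patch histogram the comparison plots is
over both signs.

Because the p-value is exact, `P(p <= alpha) <= alpha` holds by
construction; the discreteness of the statistic makes the test slightly
conservative. The acceptance suite calibrates this on 1000 independent
noise-only pairs of 100 points.

`compare_profiles()` deliberately refuses to interpolate: the two profiles
must already live on a common q grid (after optional restriction to a
`q_range`). Interpolation would correlate neighboring points and invalidate
the coin-toss null. If every point ties exactly the comparison is degenerate
and raises an error; the beam-center scanner, which legitimately encounters
this on noiseless synthetic input, treats that case as "indistinguishable"
(p = 1).

# Beam-center verification

Isotropic solution scattering is centro-symmetric about the direct beam. A
wrong beam center therefore shows up as a systematic difference between
azimuthal averages taken in two opposing pie slices ("line cuts") at very
low angle — by default from the first usable bin out to q = 0.05 Å⁻¹, where
the intensity varies steeply and a small center error is most visible.

`center_scan()` compares the two opposing cuts three times: aligned, and at
relative index offsets of ±1 point on the (uniform) q grid. The offset
realizes a small center displacement: moving the center by d pixels along
the cut axis moves one cut's effective radii by +d and the other's by −d, a
relative misalignment of 2d pixel-equivalents, so on the default grid (step
= 2 pixel-equivalents) a one-index offset corresponds to a one-pixel center
displacement. Working with index offsets on the already-binned cuts costs
one comparison per shift instead of three re-integrations of the image.

The decision rule is: recommend *keep* when the aligned comparison has the
(weakly) largest p-value; otherwise recommend the shift with the largest
p-value; report *inconclusive* when all three p-values are at least 0.5 or
fewer than 10 points survive tie removal. The rule is this package's own —
what a human does when looking at the three patch histograms — and the
verdict records all three comparison results so the user can inspect the
evidence. No multiplicity correction is applied across the three shifts;
the p-values are reported per shift, as they would be plotted.

Sign convention: for the vertical axis, `shift_plus` means the true center
sits at a larger row coordinate (further down the image) than assumed; for
the horizontal axis, `shift_plus` means a smaller column coordinate. The
mirror property (negating the planted offset flips the recommendation) is
enforced in the test suite.

# Automated buffer-subtraction scaling

Buffer subtraction at a beamline that matches sample and buffer on the
water peak near q ≃ 2 Å⁻¹ faces a systematic bias: protein also scatters
under the water peak, so after matching, the buffer is slightly
over-weighted and must be scaled back down — historically by hand, by a
factor of roughly 0.995. `estimate_scaling_factor()` automates this with
two empirical over-subtraction criteria evaluated on
`I_sub(q) = I_sample(q) − f · I_buffer(q)`:

* **Criterion 1** — the subtracted intensity must be non-negative
  everywhere, and `q·I_sub` must not have an interior local minimum under
  the water peak. A scooped-out minimum at the peak position is the
  signature of removing more water scattering than is present. The factor
  q compensates the slight overall decay of intensity with q, so a genuine
  dip is not masked by the trend. The minimum search uses strict
  three-point interior minima after optional 3-point smoothing.
* **Criterion 2** — the log10 span between the highest and lowest positive
  intensities over q > 0.3 Å⁻¹ (where no structural features exist) must
  not grow by more than `span_threshold` (default 0.05 decades) relative to
  the baseline, taken as the span of the subtraction at the starting
  factor. Carving the minimum toward zero blows up the dynamic range,
  which is the other face of over-subtraction.

The search is coarse-to-fine: starting from f = 0.9 the factor is raised in
steps of 0.01; when a criterion fires the search backs off to the last
feasible factor and divides the step by 10, terminating at a precision of
1e-4 or at the cap f = 1.0 (a matched buffer is never scaled *up*; reaching
the cap is reported as `max_factor_cap`, which is also the expected outcome
for a buffer subtracted from itself). The full trace of tested factors and
their violation flags is kept in the result, and the suite asserts
equivalence with a brute-force scan of the whole 1e-4 grid.

## Numerical choices worth knowing

* **`dip_window` vs `water_window`.** Peak matching uses the full window
  [1.8, 2.2] Å⁻¹; the minimum search uses a narrower default,
  [1.95, 2.05] Å⁻¹. The distinction matters: while still
  *under*-subtracted, the residual (positive) water peak has a local
  minimum at its trailing edge — where the decaying Gaussian flank hands
  over to the rising background of `q·I` — and that minimum sits just
  beyond one peak-width from the center. Searching all of [1.8, 2.2] lets
  it graze the window edge over a narrow band of factors, which makes
  feasibility non-monotone and biases the estimate low. Restricting the
  search to the core of the peak keeps the test specific to the
  over-subtraction dip, which always forms at the center. Both windows are
  configurable in `scaling_options()`.
* **Perfect subtraction.** An identically zero residual has no positive
  values above 0.3 Å⁻¹; it is treated as feasible (nothing left to
  violate), not as a degenerate span violation. Negative-only residuals
  remain violations.
* **Reported precision.** The returned factor is snapped to the configured
  precision grid, so results are comparable across runs and against the
  grid-search oracle.

# The synthetic-data generator

All planted-truth tests rest on `synth_params()` and its generators. The
model, and the reasoning behind each default:

* **Buffer**: baseline 1 (arbitrary units) + weak power law
  `0.05·q^−0.2` + Gaussian water peak of amplitude 1.0 and width 0.1 Å⁻¹
  at 2.0 Å⁻¹. A solvent/empty-cell curve is flat-ish with a prominent
  water peak; exact proportions are not critical, but the peak must
  dominate the window used for matching.
* **Protein**: `i0 · P_sphere(qR)` with R = 20 Å and i0 = 0.03, plus a
  flat wide-angle level of 0.003. The sphere form factor
  `P(x) = [3(sin x − x cos x)/x³]²` is a closed form with known limits
  (P(0) = 1, first zero at x ≈ 4.493), which makes it a good oracle for
  tests. The flat term stands in for the near-constant wide-angle level of
  real protein scattering; it is what water-peak matching over-weights,
  and without it the entire "scale the buffer back down by ~0.995"
  situation cannot arise.
* **Sample**: `protein + c · buffer + noise` with planted mixing factor
  `c` (default 0.995) recorded in the profile's truth attribute.
* **Noise**: Poisson on `counts = intensity × counts_per_intensity`,
  rescaled back, with σ = √counts/scale; a Gaussian approximation is used
  above 10⁶ expected counts where integer Poisson sampling is both
  unnecessary and unrepresentable. The default conversion (1e12) emulates
  profiles that are already azimuthal averages over many pixels and
  exposures, so counting error sits well below the structured signals the
  criteria look for. The generator does *not* emulate raw-frame noise,
  inter-frame drift, radiation damage or detector artifacts — passing
  tests say nothing about those.
* **2-D patterns**: an isotropic sphere-form-factor intensity
  (R = 60 Å, 2000 peak counts + 10 background) mapped about a planted
  center on a 200×200 detector at λ = 1 Å, 10 m distance, 1 mm pixels,
  with per-pixel Poisson noise. At these settings q = 0.05 Å⁻¹ sits ~80
  pixels from the center and the intensity falls several-fold across the
  verification range, which is what makes a one-pixel center error
  visible; the cut grid uses a step of 2 pixel-equivalents so that the
  planted one-pixel offset is exactly realigned by a one-index shift.
* **Spreadsheets**: each plate row carries a buffer in well 1 serving the
  samples in wells 2–5 and a second buffer in well 6 serving wells 7–9,
  so every buffer serves at most five measurements and lives in the same
  row pair (hence the same holder) as its samples. Planted rule
  violations mutate a clean sheet in exactly one way each.

# Logistics conventions

The measurement-sheet and plate-sheet schemas are documented under
`?sheets`. Validation is pure (the same sheet always yields the same
report) and never mutates on failure; on success it embeds the user
information and a fresh v4 UUID per holder, drawn from R's RNG so tests
can fix the sequence with `set.seed()`.

Transfer planning maps plate rows pairwise onto 18-position holders
(row 2k−1 → positions 1–9, row 2k → 10–18), which is also why the plate
convention reserves only 9 of 12 wells per row for measured samples: two
full rows fill one holder. Mixing steps for a well precede its final
transfer, and the final transfer carries the mix flag. Deck planning
allocates 12 standard-plate slots among plates, three-holder adaptors and
tip racks; the worst-case planning budget of 3 tips per occupied well
(transfer plus up to two mixing aspirates, fresh tip each) prices a
two-plate run at 6 racks, leaving 4 adaptor slots = 12 holders, the
configured per-run maximum. Actual runs count tips from the sheet's real
mixing steps under a configurable policy (one tip per source well by
default). The storage unit holds 20 holders (360 samples); the manifest
compiler enforces this and requires every holder UUID to resolve to
exactly one owner and sheet before collection starts.

# Problem sizes and determinism

The test suite and the acceptance script use: exhaustive enumeration up to
n = 16 for the null distribution; 1000 noise-only pairs of 100 points for
calibration; 100 patterns each for planted-offset and true-center
verification; and 100 sample/buffer pairs with planted factors in
[0.992, 0.998] for the scaling estimator, each cross-checked against the
full 1e-4 grid scan. All generators are pure functions of (parameters,
seed); every stochastic test fixes its seeds.

# Known limitations

* The comparison statistic assumes exchangeable noise between the two
  curves; correlated noise (shared systematic errors) breaks the coin-toss
  null.
* Beam-center verification detects offsets along the tested axis at the
  granularity of the cut grid; it verifies rather than refines (no
  sub-pixel fitting), and assumes an isotropic scatterer.
* The scaling criteria are empirical. They assume the subtracted data are
  smooth beyond 0.3 Å⁻¹ and that over-subtraction manifests at the water
  peak; strongly structured wide-angle scattering or a mis-matched q grid
  will mislead them.
* The logistics layer validates and plans; it does not drive hardware,
  decode QR images or print labels.
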