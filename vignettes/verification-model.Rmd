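---
title: "A film-fed verification model for VMAT deliveries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A film-fed verification model for VMAT deliveries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcqa)
```

## The problem

Volumetric modulated arc therapy (VMAT) delivers radiation while the
gantry, the multi-leaf collimator (MLC) and the dose rate all change
continuously. Treatment planning systems describe the arc with a discrete
sequence of control points (CPs), so two distinct uncertainties separate
the planned from the delivered dose: the accuracy of the dose calculation
itself, and the mismatch between a discrete calculation and a continuous
delivery. Machine log files record what the linac actually did
(time-stamped gantry angles, leaf positions and cumulative monitor units,
MU), but a calculation from the log is still only a calculation: it needs
experimental feedback.

`arcqa` implements a verification model built around a cylindrical PMMA
phantom that hosts radiochromic film rolled at two radial depths (an outer
scroll at 10 mm depth and an inner scroll at 60 mm), plus an ionization
chamber at the isocenter. The rolled film measures dose continuously
around the whole arc with sub-millimetre resolution; the model uses those
measurements to *re-weight the per-CP monitor units* of the log-file
calculation, and the adjusted weights then reconstruct the delivered dose
and DVH on the patient grid.

## The monitor-unit adjustment

Let `C` be the matrix whose column `j` holds the dose per delivered MU of
control point `j` at every measurement location (film-scroll samples plus
the chamber point), `mu` the per-CP MU read from the log, and `d` the
stacked measured doses. The adjustment solves, for per-CP multiplicative
weights `x` (1 = log value),

```
minimize   0.5 || C diag(mu) x - d ||^2
subject to |C diag(mu) x - d| <= tol        (per measurement row)
           sum_j mu_j x_j = total MU        (equality)
           lb <= x <= ub                    (per-CP bounds, default 0.90-1.10)
```

The equality constraint pins the machine's total-output counter, which is
independently calibrated; the bounds restrict each CP to small relative
changes, so the fit cannot simply re-invent the plan; and the per-row
tolerance (default: the larger of 3% of the local dose and 0.02 Gy)
declares how much residual disagreement is acceptable, acknowledging that
a film pixel averages the heterogeneity of several overlapping apertures.
Because neighbouring CPs irradiate overlapping film regions, the fit is
resolved mostly through that lateral overlap, which is exactly the
information a discrete calculation misplaces.

The solver is a dual active-set quadratic program (`quadprog`), which is
deterministic and reproducible. Two numerical choices matter:

* a Tikhonov stabilizer (default `1e-8` of the mean normal-matrix
  diagonal) is biased toward `x = 1`, so that among near-optimal solutions
  of an ill-conditioned fit the smallest MU change is preferred — never
  the smallest MU;
* if the tolerance rows make the problem infeasible, the tolerance is
  relaxed by factors of 1.5 with an explicit warning per step (up to 8
  steps), and a structured infeasibility report is produced if relaxation
  is exhausted. Nothing is relaxed silently.

If the starting point `x = 1` is feasible, the solution's objective can
never exceed it: the adjustment is never worse than doing nothing.

## Log files and discretization

The supported log dialect is CSV with columns `time_s, gantry_deg, mu_cum,
beam_on, leaf_a_*, leaf_b_*` (leaf positions in mm at the isocenter
plane). Gantry angles follow IEC 61217; arcs may cross 0/360 and are
unwrapped internally. Parsing is strict: non-monotone cumulative MU,
crossed leaves, or out-of-range angles are integrity errors that name the
offending record.

Two discretization levels turn a log into a CP sequence:

* **coarse** — one CP per record with a positive MU increment, carrying
  that record's angle and leaves. Positions are recorded at 4 Hz while
  the machine's MU counter updates more slowly (the generator models a
  1 Hz counter), so most records repeat the previous cumulative MU and
  are excluded; a realistic 60 s arc yields roughly 60 coarse CPs, the
  same scale as a clinical plan's CP list.
* **fine** — each coarse interval is subdivided into equal-MU sub-CPs,
  the sub-CP count proportional to the interval's share of total MU with
  a floor of one. CP density per degree is therefore proportional to the
  local MU-per-degree rate (the dose rate is built into the sampling),
  the coarse boundaries are retained (fine strictly refines coarse), and
  the default multiplier of 3 gives about three times the coarse count.
  Apertures at off-record boundaries are interpolated linearly in time,
  the standard assumption for dynamic MLC motion.

Both levels conserve total MU exactly (tested to 1e-9 MU).

## The dose engine

The per-CP dose calculation is a deterministic divergent-beam engine:
dose per MU at a point is `fluence(u, v) * mu_to_gy *
exp(-mu_att * radiological_depth)`, where `(u, v)` are the point's
beam's-eye-view coordinates projected to the isocenter plane, the fluence
is 1 inside the MLC aperture and `leaf_transmission` (default 1.5%)
beneath closed leaves with a Gaussian penumbra (`kernel_sigma`, default
3 mm at the isocenter plane), and the radiological depth is ray-marched
through the density grid from the source (1 mm steps by default).
Attenuation uses an effective coefficient of 0.005/mm water-equivalent,
representative of 6 MV. Inverse-square falloff is intentionally omitted:
the engine's attenuation law along any ray is then exactly exponential,
which keeps closed-form checks exact; absolute dose scale is absorbed
into `mu_to_gy`.

This engine is *not* a transport calculation — it stands in for one. What
the verification model actually consumes is the linear structure: dose is
strictly linear in MU, CPs superpose, and the pattern rotates rigidly
with the gantry (all three are tested, the rotation to 1e-10 on a
symmetric grid). `build_contribution_matrix()` accepts arbitrary sample
points, so externally calculated per-CP doses could replace the engine
without touching the adjustment. Monte-Carlo-like statistical noise
(independent Gaussian, relative sigma below 1%) can be injected
reproducibly with `add_statistical_noise()` to emulate the statistical
character of a real MC calculation.

## Phantom, scrolls and films

`build_phantom()` voxelizes the two phantom setups (big: 300 mm diameter x
300 mm; small: 200 mm x 280 mm; PMMA density 1.19 g/cm^3, air outside).
`extract_scroll()` unrolls a cylinder of radius `r` from a 3-D dose grid
by trilinear interpolation every 0.5 degrees of azimuth (configurable),
giving a z-by-azimuth image whose pixel width is `r * dtheta` in radians —
0.7854 mm for the outer scroll (r = 90 mm) and 0.3491 mm for the inner
(r = 40 mm) at 0.5 degrees. Azimuth zero is the gantry-zero entrance
direction and increases with gantry angle, which fixes the film-to-scroll
correspondence. `scroll_ensemble()` averages five extractions (unshifted
plus one-voxel isocenter shifts along each transverse axis), folding the
one-voxel positional uncertainty between calculation grid and physical
film into the reconstructed scroll; min/max envelopes are retained, and
the declared positional uncertainty is the in-plane voxel pitch (1.25 mm
on the default grid).

The film model uses the rational sensitometric form `v(D) = a + b/(D - c)`
per colour channel (monotone and pole-free over the calibrated 0-400 cGy
range with `b > 0`, `c < 0`), fitted to 16 or more calibration points by
Levenberg-Marquardt (`minpack.lm`). Dose conversion is multichannel: per
pixel, dose `D` and a common multiplicative disturbance `delta` (film
thickness, scanner gain) are chosen to minimize the squared residual
across the three channels; for fixed `D` the optimal `1 + delta` is
closed-form, so the search is a fast 1-D minimization. Constraining
`delta = 0` reduces exactly to green-channel inversion. Lateral scanner
non-uniformity is corrected per column; the longitudinal direction is
left untouched. Film-to-calculation alignment uses an exhaustive
mutual-information search (64-bin joint histogram, 0.5 px / 0.25 degree
grid, then two refinement levels down to 0.125 px). MI is evaluated on a
fixed interior region so that every candidate transform compares the same
number of samples — sparse-histogram MI estimates are biased upward, and
without this the search systematically favours large transforms with
small overlap. Candidates are visited in order of increasing transform
magnitude so exact ties resolve to the identity. For full-turn scroll
images the azimuth axis is treated as periodic: an azimuthal offset of a
rolled film is a rotation of the roll, not a crop.

## Comparison metrics

`percent_dose_difference()` and `gamma_map()` implement the standard film
QA metrics: global percent difference (normalized to the reference
maximum) with a <3% passing criterion, and the gamma index at 2%/2mm
(and 3%/3mm) with a 20% low-dose threshold applied to the reference.
The gamma search upsamples the reference 4x bilinearly and caps the
spatial search at 3 x DTA; any pixel whose capped minimum exceeds the
cap's distance-only bound is re-searched exhaustively, so the optimized
result equals the exhaustive minimum everywhere — an equivalence the test
suite checks against an independent brute-force oracle (written in C++ as
a plain triple loop) to 1e-9. Gamma exactly 1.0 counts as passing, so the
textbook boundary case (a uniform offset of exactly the dose criterion on
a flat field) passes at 100%.

## The synthetic scenario generator

Because the original films and logs of any clinical delivery are not
reproducible at a desk, the package ships a seeded generator whose
defaults define the study conditions:

* **plans** — single arcs with 34-93 equi-spaced CPs (presets mirror a
  prostate-like 87-CP/360-degree arc, a head-and-neck-like 93-CP arc and a
  34-segment static control), smoothly varying random apertures and MU
  (low-order Fourier series along the arc, so neighbouring CPs overlap
  laterally), 500 MU total by default;
* **delivery** — 4 Hz records at constant gantry speed (6 deg/s default)
  with a 1 Hz MU counter; delivery errors are a smooth multiplicative MU
  drift (sum of up to three random-phase sinusoids, nominal amplitude 5%,
  normalized so total MU is conserved — the machine's output counter is
  trusted, its distribution over the arc is not), plus 0.5 mm leaf jitter
  and 0.2 degree gantry jitter. The drift defines the ground-truth
  weights `x*` the pipeline must recover; a zero error model replays the
  plan exactly and has `x* = 1`;
* **measurements** — true dose (drift-weighted CP contributions) at the
  film sample locations is pushed through the film forward model:
  response curves, a 3% parabolic lateral scanner profile, 0.3% scanner
  noise, 16-bit quantization, and a small random rigid offset per film
  (up to 1 mm / 0.3 degrees by default). The outer scroll is split into
  two films (upper/lower halves), the inner is one film, and the chamber
  reading adds 0.5% noise. Everything is reproducible bit-for-bit under a
  fixed seed.

Desk-scale sizes keep runtimes in minutes on one CPU: phantom grids at
2.5 mm voxels, film images at 2 degrees azimuth and 2.5 mm axially, and
measurement assembly downsampled by 2 with a 20% dose threshold. The
methods do not depend on these sizes; they are the documented defaults of
the generator and pipeline.

The synthetic film dose is evaluated at the film sample points through
the same point-evaluation path used to build `C`, rather than through a
voxelized grid, so that the zero-noise pipeline closure (recovering `x*`)
is exact up to film quantization. Grid extraction and the shift ensemble
remain the path for grid-based dose maps and are tested separately.

## What passing tests do and do not show

The generator emulates per-CP dose linearity, MC-like noise, the film
response chain and rigid misregistration. It does **not** emulate real
radiation transport (scatter, spectrum, leaf-end effects), film
post-irradiation kinetics, scanner artefacts beyond the lateral profile,
or deformable film distortion. A green suite therefore demonstrates that
the *pipeline* — discretization, linear dose bookkeeping, film
processing, registration, constrained adjustment, DVH reconstruction —
is internally correct and robust to the stated noise levels, not that any
clinical passing rate would be reproduced.

Known limitations worth stating plainly:

* with the default film misregistration enabled, the registration
  residual (about a third of a scroll pixel) injects correlated dose
  errors that the adjustment partially chases; in about 3 of 20 noisy
  scenarios whose true delivery error happens to be small, the adjusted
  reconstruction is then slightly *further* from truth than the log
  reconstruction. At the nominal noise conditions with films placed at
  the phantom's reference marks, the adjustment improves all 20 of 20
  seeded scenarios;
* per-CP weights are only weakly identifiable when CP apertures overlap
  heavily; the stabilizer returns the smallest-change solution, and the
  meaningful outputs are the reconstructed dose and DVH rather than any
  single CP's weight;
* the printed inner-scroll pixel width of an effective 40.4 mm radius is
  reproduced here with the nominal 40 mm radius (0.3491 mm rather than
  0.3523 mm); the discrepancy — film thickness or measurement-radius
  convention — is noted, not resolved.

## A worked example

```{r example, eval = FALSE}
library(arcqa)

sc <- make_scenario("prostate-like", seed = 1)
res <- run_verification(sc)
res
#> <verification_result> 60 CPs (coarse) | max |MU change| 10.00% |
#>   RMS vs truth: log 0.009071 Gy -> adjusted 0.003222 Gy

# angular MU differences (adjusted - log), summing to zero
rep <- mu_change_report(res$solution, res$arc)
sum(rep$binned$dmu)

# reconstruct the adjusted dose on a synthetic patient and compare DVHs
pat <- make_patient()
Cp <- build_contribution_matrix(res$arc, pat$grid,
                                sample_rows = seq_len(prod(pat$grid$shape)),
                                model = sc$model)
Cp$voxel_index <- NULL
dose_adj <- reconstruct_dose(Cp, res$solution)
dvh <- compute_dvh(dose_adj, pat$structures$ptv)
dvh_metric(dvh, "D95")
```
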