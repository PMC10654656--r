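---
title: "Quantifying bead-based multiplex Western blots: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bead-based multiplex Western blots: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiwestr)
```

## The assay and its digital readout

In a bead-based multiplex Western blot (DigiWest-style assay), proteins are
separated by SDS-PAGE, blotted, and the lane is cut horizontally into 96
stripes of equal height. Each stripe's proteins are coupled to a distinct
color-coded bead population; the pooled beads reconstitute the lane in
suspension and can be probed with hundreds of antibodies from a single lane
equivalent. A flow-based reader reports one median fluorescence intensity
(MFI) per bead color and incubation.

Computationally, the assay therefore reduces to a family of 1-D signals:
for each sample × antibody, reassigning bead color IDs to their stripe of
origin yields a **fraction profile** — 96 ordered fluorescence values, index
0 at the top of the gel (highest molecular weight). An antibody-specific
signal appears as a peak at the fraction corresponding to the target's
molecular weight. The package's pipeline is:

1. **Lane reconstruction** (`reconstruct_lane`): a pure permutation of the
   96 MFI values via the bead map. The value multiset is conserved; missing
   or duplicated fractions are an error, never silently patched.
2. **MW calibration** (`fit_calibration`): protein migration is close to
   linear in log10(MW) on gradient gels, so the fraction↔kDa map is fitted
   as a piecewise-linear interpolation of log10(MW) against fraction index
   through the ladder anchors, extrapolated linearly beyond the outermost
   anchors and clamped to [1, 500] kDa. A spline was deliberately rejected:
   the piecewise log-linear map has an exact closed-form inverse, which
   makes the calibration testable to machine precision and keeps MW
   tolerances interpretable.
3. **Baseline estimation** (`estimate_baseline`): the assay provides two
   controls — empty beads (bead background) and a secondary-antibody-only
   incubation (nonspecific detection signal). The baseline is their
   elementwise maximum (conservative and order-independent), smoothed with
   a running median of window 3 (shrinking at the edges) so single-bead
   outliers in a control do not carve a spike into every net profile.
4. **Background subtraction** (`subtract_background`):
   `net = max(0, profile − baseline)`. Negative residuals are clipped; the
   clip count is retained for QC. Clipping keeps the accumulated intensity
   non-negative, which is what an *accumulated* fluorescence intensity
   should be.
5. **Peak detection and integration** (`detect_peaks`, `integrate_peak`):
   described in detail below. The integral of the net signal over the peak
   window is the **AFI** (accumulated fluorescence intensity), the assay's
   quantitative readout.
6. **Marker calls** (`call_markers`): the acceptance rules of the assay —
   peak height ≥ 50 AU, AFI ≥ 100 AU (both inclusive), apex MW matched to an
   expected MW within ≤ 10 kDa, and a cross-sample consistency requirement
   on the MW shift — yield a detection matrix with machine-readable failure
   reasons per cell.

## Peak detection rules

For each expected MW *m* of an antibody, the fractions whose MW lies in
*m* ± 10 kDa (the assay's MW tolerance, reused as the search radius) are
searched. The apex is the local maximum (≥ both neighbours) with the
largest net value; ties resolve to the fraction whose MW is closest to *m*,
then to the lower index.

**Boundaries.** From the apex, boundaries extend outward while the net
signal stays above τ = max(5% of apex height, 10 AU), and the boundary is
placed *on* the first fraction at or below τ. Placing the boundary on the
closing fraction (rather than just inside it) matters numerically: with the
5% threshold, stopping one fraction short systematically truncates ≈ 1.5–3%
of a Gaussian band's area, whereas the inclusive stop recovers the analytic
integral A·σ·√(2π) to well within 1% for band widths of 1–4 fractions. AFI
is the plain inclusive sum over the boundary window — by construction it
always equals a brute-force sum oracle exactly, and is never less than the
apex height.

**Splitting adjacent bands.** A local minimum below 50% of the apex height
out of which the signal rises again marks the boundary with an adjacent
peak; the valley fraction is assigned to the taller peak (ties: to the peak
on the lower-fraction side), so adjacent integration windows never overlap.

**Isoform doublets.** When an antibody expects several MWs (e.g. a 21/24
kDa isoform pair), both search windows typically contain both bands and
both elect the taller apex. The apex then belongs to the closer expected
MW, and the other window re-elects among the remaining local maxima — but a
re-elected secondary apex must reach at least 50% of the primary apex
height, the same significance level the valley rule uses. This keeps
shoulders and background bumps next to a dominant band from being promoted
to isoform peaks; the consequence, which users should be aware of, is that
a genuine isoform below half the dominant band's intensity is reported as a
single dominant peak. Two peaks are only ever reported when a sub-half
valley separates them.

No smoothing is applied to the signal before detection (only the baseline
is median-smoothed): at 96 points per lane the resolution is already
coarse, and smoothing would bias apex heights against the inclusive
height threshold.

## Marker acceptance and its edge cases

`apply_thresholds` is inclusive at both boundaries ("at least 50" / "at
least 100"): height 50 with AFI 100 passes; 49 or 99 fails with
`below_min_height` / `below_min_afi`. `match_mw` matches the nearest
expected MW, succeeding iff the distance is ≤ 10 kDa (a 10 kDa shift
matches; 11 does not); equidistant isoforms resolve to the lower MW.

`check_consistency` operationalizes "the shift must be consistent in all
samples": across all threshold-passing peaks of one antibody, every peak
must match an expected MW and the spread of signed shifts (max − min) must
not exceed 5 kDa. The 5 kDa spread is a package parameter
(`spread_kda`) — the underlying assay rule states the concept but no
number. Consistency is evaluated within one run; cross-batch pooling is out
of scope.

Two edge cases deserve attention:

* **High-MW quantization.** One fraction spans ~0.7 kDa at 20 kDa but ~8
  kDa at 230 kDa on the default ladder. A one-fraction apex jitter under
  noise can therefore exceed the 5 kDa spread for high-MW markers
  (e.g. fibronectin) and flag the antibody inconsistent in a minority of
  runs. This is a faithful consequence of stating the rule in kDa; widening
  `spread_kda`, or stating it in fractions, are the obvious remedies for
  high-MW panels.
* **Threshold monotonicity.** Raising `min_height`/`min_afi` can never turn
  a cell from not-detected to detected *as long as the antibody's
  consistency verdict is unchanged*; in the contrived case where raising a
  threshold removes the one shifted peak that made an antibody
  inconsistent, the remaining cells can flip to detected. The package
  implements the consistency rule exactly as stated and documents rather
  than hides this interplay.

Species validity is a property of the panel file (`valid_species`), not
inferred from data: a sample whose species an antibody was never validated
for yields a *not-applicable* cell, distinct from not-detected.

## The synthetic-data generator

No public instrument exports exist for this assay, so the package ships a
generator (`simulate_dataset`, `simulate_sec_series`) that emits complete,
self-consistent runs — readout, bead map, ladder, controls, panel, sample
sheet — together with the exact ground truth of every emitted band. Each
lane is

> baseline + secondary bump + Σ Gaussian bands + N(0, noise_sd), clipped at
> 0, rounded to 4 decimals.

Bands are Gaussian in *fraction* space (the simplest shape with an analytic
integral, A·σ·√(2π), which the truth table records as `true_afi`); centers
come from the band's true MW through the same ladder calibration the
pipeline uses. Noise is additive Gaussian clipped at zero.

Defaults, chosen once as order-of-magnitude realistic values (the assay's
real noise magnitudes and baseline levels are not published):

| parameter | default | rationale |
|---|---|---|
| baseline_level | 100 AU | typical empty-bead MFI background |
| amplitude | 500 AU | ≈10× the 50 AU height rule: a clearly detectable mid-panel band |
| noise_sd | 25 AU | 5% of amplitude; typical background variability |
| width (σ) | 1.2 fractions | 0.5 mm stripes; bands span ~5 fractions |
| secondary bump | fraction 78, 40 AU, σ 6 | broad low nonspecific signal in the low-MW region |
| ladder | 8 anchors, 250 kDa (fraction 2) → 10 kDa (fraction 93), log-linear | gradient-gel-like span |

The default experiment emulates a three-species EV characterization: 15
antibodies (nine general EV markers, three restricted markers, three
coisolation indicators), with CD9 carrying a consistent −8 kDa true shift
(a band reproducibly below its nominal weight — the situation the
consistency rule exists to accept). Expected MWs are field-standard values
for these proteins; they are synthetic stand-ins, not measured assay
values. The SEC preset derives one lane set per pooled size-exclusion
fraction set ("5-7" … "20-22"), scaling amplitudes by per-marker enrichment
weights centered on the "8-10" and "11-13" sets, with a coisolated
ribosomal marker restricted to those sets.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: bead-coupling chemistry and antibody
cross-reactivity (off-target bands at unrelated MWs), signal-dependent
(multiplicative) noise, plate and batch effects, saturation, gel-migration
anomalies beyond a monotone MW↔fraction map, and carry-over between
fractions. Recovery statistics on synthetic data are upper bounds on
real-data performance.

## Problem sizes and determinism

The test suite and the acceptance script run, per invocation: the
three-sample × 15-antibody panel noiselessly and across 20 noisy seeds at
noise = amplitude/20 (900 matrix cells), ~500 randomized lanes for the
AFI-oracle identity, 20 further seeds (~660 peaks) for apex-MW recovery,
one six-set SEC series, and the two-anchor calibration checks — a few
minutes on one CPU. All randomness flows through explicit integer seeds;
`simulate_dataset` restores the caller's RNG state, and a fixed
configuration + seed reproduces every artifact byte-for-byte (text tables
use a canonical 15-significant-digit format; MFIs are rounded to 4 decimals
at generation, so generated fixtures round-trip exactly).

## Known limitations

* AFI values are comparable across fraction sets of one lane series, but
  band intensities in Western-blot mimics are normalized per lane by
  default and must not be compared across samples (`normalize = "figure"`
  exists for the cases where a common scale is wanted).
* Heavily overlapping bands are not deconvolved by model fitting; the
  valley rule is a deterministic geometric split.
* Per-bead CVs, outlier beads within a fraction, and plate-effect
  normalization are out of scope; the readout model starts from one MFI per
  fraction.
* The acceptance rules use the assay's published constants (50 AU, 100 AU,
  10 kDa); they are parameters of `call_markers`, and panels whose bands sit
  near these limits will be sensitive to them.
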