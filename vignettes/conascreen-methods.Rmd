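---
title: "Quantifying on-bead fluorescent rings: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying on-bead fluorescent rings: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its read-out

In on-bead confocal nanoscanning (CONA), a population of sieved agarose
beads carrying a surface-immobilized bait is imaged in a single confocal
plane. Because the bound fluorophores sit on the bead surface, the optical
section through a bead shows a bright **ring** at the bead's circumference.
In the RNA pull-down variant (RP-CONA) two channels are read: a reference
channel reporting the immobilized, fluorescently tagged RNA (e.g. FITC) and
a signal channel reporting a fluorescent-protein-tagged RNA-binding protein
captured from cell lysate (e.g. mCherry). The per-bead read-out is the
ratio of signal to reference ring intensity; an interaction inhibitor
lowers the protein ring without touching the RNA ring, so the ratio falls.

`conascreen` implements the full downstream analysis -- bead detection,
ring quantification, well aggregation, plate QC, hit calling and IC50
fitting -- together with a synthetic image generator that provides ground
truth for validation.

## The synthetic image model

A scene is a set of beads with diameters drawn from a normal distribution
truncated to the sieving window $[100, 120]\,\mu m$ (mean 110, SD 4 by
default), placed by rejection sampling so that center distances are at
least 1.05 times the sum of radii (overlapping scenes are an opt-in stress
mode). The noiseless pixel model per channel is

$$I(p) = b + c\,[d(p) \le R] + A\,e^{-(d(p)-R)^2 / 2\sigma_r^2},$$

with background $b$, optional interior (lumen) fill $c$ (default 0), ring
amplitude $A$ and radial ring width $\sigma_r$ (default $3\,\mu m$). Bead-
to-bead amplitude variation is Gaussian (truncated at zero) with a default CV of 5%.
Optional Gaussian optical blur is applied to the noiseless image, then
Poisson shot noise and additive Gaussian read noise (SD 5 AU by default).
Default amplitudes (reference 800 AU, signal 400 AU over background 50 AU)
put the peak signal-to-noise ratio well above 10, which is the regime the
validation studies target.

The defaults represent deliberate assumptions where the assay description
gives none: pixel pitch is fixed at $1\,\mu m$/px (beads are then ~110 px
across, matching a 20x air objective on a large-chip camera to within a
small factor), and the interior level defaults to zero so that the
ring-intensity ratio of two channels equals their amplitude ratio exactly.
Real bead images show a faint interior fill, which is why the interior
level is configurable. The generator renders a single plane only -- no 3-D
PSF, no compound autofluorescence, no bead degradation -- so passing tests
demonstrate correctness of the *measurement chain*, not robustness to
every artifact of real microscopy.

A simulated plate adds a ground-truth binding model: the bound fraction of
the tagged protein follows a four-parameter logistic (4PL) curve of the
compound dose, negative-control wells sit at the curve's top, positive
controls at a stated residual bound fraction (default 0.29, matching a
strong competitor), and the signal-channel amplitude of each well is the
base amplitude times the bound fraction. The reference channel never
varies with dose.

## Bead detection

The detector runs on the reference channel, because every non-blank bead
carries RNA; beads without an RNA ring ("blank beads") are invisible to it
and therefore never measured. The algorithm is: Gaussian smoothing (sigma
2 px), Otsu threshold on the min-max-normalized image (making the result
invariant to overall intensity scale), hole filling so each ring becomes a
disc, watershed splitting on the distance map (separating touching beads;
the watershed tolerance of 0.3 times the minimum expected radius prevents
oversplitting single beads), and connected-component analysis. Each
interior component yields a centroid and a radius taken from the peak of
its radial intensity profile, refined parabolically to sub-pixel
precision. Components clipped by the image edge are instead circle-fitted
algebraically (Kasa fit) on their ring-band pixels, which remains accurate
for partial arcs.

Quality control never silently drops a bead: loci carry `border`,
`overlap` and `size_out_of_range` flags and are excluded at measurement
time, keeping the audit trail intact. Heavily fused bead masses that the
watershed cannot separate are caught by a circularity check (component
area vs. $\pi R^2$) and flagged `overlap`; declumping them is out of
scope.

## Ring quantification

Three chords at 0, 60 and 120 degrees are sampled through each bead center
by bilinear interpolation (three measurements across each ring, the
assay's standard design). On each side of the center the peripheral peak
is the profile maximum within the annular window $R \pm 0.2R$, refined by
a local parabolic fit. The per-channel ring intensity is the mean of the
available peak heights minus the field background (median of pixels
farther than radius + 10 px from every bead), clamped at zero; at least 4
of the 6 peaks must exist. An integrated-annulus statistic (mean intensity
over $R \pm 0.2R$) is available as a configuration alternative, as is a
raw (non-background-subtracted) mode -- the peak statistic with background
subtraction is the default reading of the assay.

The ratio is formed per bead and averaged per well (not the ratio of well
means), preserving the per-bead distribution the on-bead assay provides.
A bead whose reference ring intensity falls below 50 AU after background
subtraction is recorded as invalid with reason `blank_bead`; the ratio is
never a division by zero.

## Plate statistics, QC and hit rules

Wells are summarized by the mean and sample SD (n-1) of the ratio over
valid beads, with a per-well floor of 50 valid beads by default (the assay
pools hundreds of beads per control analysis across a handful of wells;
the per-well floor is our choice). Control statistics are **between-well**:
mean, SD and CV (100 SD/mean) across replicate control wells. For
single-well screens a between-bead SD fallback exists but must be enabled
explicitly and is flagged in the QC report.

The screening window is
$$Z' = 1 - \frac{3\,(SD_{pos} + SD_{neg})}{|\,\overline{x}_{pos} - \overline{x}_{neg}\,|},$$
undefined for equal means, equal to 1 in the noiseless limit, and invariant
under scaling and shifting of all well values. Wells are normalized to the
negative-control mean; percent inhibition is $100(1 - \text{relative ratio})$.

Two hit rules are implemented, matching established screening practice:
rule A flags wells whose relative ratio falls below the negative-control
mean minus 3 between-well SDs; rule B flags wells whose percent inhibition
exceeds 6 times the negative-control CV. Ratio-increasing wells
(stabilizers) are flagged separately above the symmetric upper band; the
screen itself targets inhibitors.

## Dose-response fitting

Concentration-response data are fitted with the 4PL model
$y = bottom + (top - bottom)/(1 + (x/IC50)^{hill})$ by Levenberg-Marquardt
least squares with an analytic Jacobian. The IC50 enters the optimization
as $\log IC50$ by default -- better conditioned on log-spaced doses; a
linear parameterization is available and recovers the same optimum on
clean data (a tested invariant, along with exact dose-scale equivariance).
The analytic Jacobian matters in a subtle way: finite-difference steps
proportional to a parameter's magnitude degenerate when $\log IC50$
happens to sit near zero (IC50 near 1), which is a perfectly ordinary
dose range.

Starting values are: top = max response, bottom = min response, IC50 =
geometric mean of the doses bracketing the half response, Hill slope 1.
Standard errors come from the curvature of the objective at the optimum;
the IC50 SE under the log parameterization is mapped back by the delta
method. Fit SEs are what the package reports; when replicate runs exist,
the between-replicate SD of independent IC50 estimates is a useful
complementary spread, and nothing prevents computing it from repeated
`fit_4pl()` calls. A fit is marked `reliable = FALSE` when the IC50 SE
exceeds the IC50 or when no observed dose samples the transition region
(20--80% of the fitted span): a pure two-level jump fits arbitrarily steep
curves whose IC50 is an artifact of dose placement. The Hill slope is
freely fitted; there is no weighting by replicate SD.

## Validation study sizes

The test-suite studies were sized to exercise every claim at desk scale:
detection and geometry are validated on a standard 20-bead
$1024 \times 1024$ px scene; ratio recovery on 108 noisy beads (nine
900 px fields of 12 beads); linearity on a noiseless six-point amplitude
sweep; the end-to-end screen on a 6 negative + 6 positive + 1 compound
plate of 640 px, 12-bead fields with a per-well floor of 6 beads for that
study (the package default of 50 presumes production-size wells); the
rule-A null false-positive rate on five simulated plates of 12 negative
controls plus 100 null wells each (500 null wells total), simulated at the
bead-measurement level since the hit rules operate on measurement tables
and the image path is covered by the end-to-end study; and 4PL recovery on
100 seeded noisy refits of an 8-dose design.

## Known limitations

* The generator's noise model (Poisson + Gaussian read noise) and interior
  level are assumptions, not measured camera statistics; real instruments
  add fixed-pattern noise, vignetting and focus drift that the simulator
  does not emulate.
* Detection assumes approximately circular rings of a narrow size range;
  heavily fused bead masses are flagged and excluded rather than split.
* Single-plate analysis only: no multi-plate batch normalization (B-score
  and relatives are out of scope).
* Brightfield channels, when acquired, are ignored by the quantification.
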