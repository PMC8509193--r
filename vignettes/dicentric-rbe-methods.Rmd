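---
title: "Methods: dicentric aberration Monte Carlo and mixed-field RBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dicentric aberration Monte Carlo and mixed-field RBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dicentra` predicts dicentric chromosome aberrations in human peripheral
blood lymphocytes (PBL) and the resulting relative biological effectiveness
(RBE) of therapeutic ion beams.  The model rests on three assumptions:

1. Radiation induces **critical lesions** (CLs): chromatin breaks severe
   enough to split a chromosome into independent fragments.  The CL yield is
   *not* derived from track structure; it is the model's single adjustable
   parameter, expressed per micrometre of ion path (ions) or per Gy per cell
   (photons).
2. Fragment free ends **mis-rejoin** with a probability weight that decays
   with their initial spatial separation, `P(r) = exp(-r/r0)`, or remain
   permanently unrejoined.  `r0 = 0.8` μm for lymphocytes.
3. Mis-rejoining patterns are classified into cytogenetic categories:
   **dicentrics** (linear element, two centromeres), **centric rings**
   (cyclic element, one centromere), and **visible deletions** (acentric
   elements above a size threshold).

### Geometry and lesion placement

The nucleus is a sphere of radius 3 μm (typical lymphocyte nucleus; a
configuration parameter).  Ion tracks are straight lines parallel to the
beam axis; their number is Poisson with mean `Φ·πR²`, where the fluence
`Φ = D / (0.1602·LET)` follows from the standard microdosimetric identity at
unit density.  CLs are Poisson along each chord (ions) or uniform in the
nuclear volume (photons).  Delta-ray spread and track substructure are
deliberately ignored: the per-micrometre CL density absorbs them.

Chromosome identity uses the packaged human female (46,XX) karyotype, by
default **content-weighted** (probability ∝ Mbp).  An optional
**voronoi_territories** mode samples 46 uniform seed points and assigns each
lesion to the nearest-seed territory, giving spatial chromosome locality.
Both modes are declared approximations of interphase chromosome-territory
architecture, not reconstructions of any specific published geometry.  The
photon CL yield is referred to the full diploid genome (per-cell), a
documented convention choice.

### Rejoining and classification

Free ends are visited in uniformly random order; each still-undecided end
draws a partner among all other undecided ends — excluding its sibling end
born at the same CL, since a CL by definition produces two *independent*
fragments (restitution is folded into the calibrated yield) — with weights
`exp(-d/r0)`, or stays permanently free with weight `c_free` (default 0.1;
its value is absorbed by the CL-yield calibration and recorded in outputs).
An element with `c ≥ 2` centromeres counts as `c − 1` equivalent
dicentrics; deletions are visible when their total length is at least 3 Mbp
(order of optical resolution of condensed chromatin; configurable).

The per-cell pipeline is implemented once in C++ and drawn from R's RNG, so
a single seed reproduces every simulation exactly.  The R-level operations
(`sample_tracks()`, `place_ion_cls()`, `fragments_from_lesions()`,
`rejoin()`, `classify()`) wrap the same internals; the test suite holds the
stochastic core against an independent pure-R exhaustive enumeration of the
sequential matching process.

## Calibration and the database

`calibrate_cl_yield()` adjusts the CL yield until simulated dicentric
dose-response curves match an observed curve in error-weighted least
squares.  The objective re-simulates with a fixed per-evaluation seed, so it
is deterministic during the golden-section search (relative tolerance
10⁻²); the bracketing grid scan runs at a reduced cell count because it
only localizes the minimum.  Weights are `1/σ²`, with Poisson-based
`σ² ≈ Y/n` when standard errors are absent.

The LET dependence of the calibrated yields is fitted per ion category,
through the origin (a per-μm yield must vanish with LET): linear-quadratic
for protons and heavy ions (Z ≥ 4), linear for helium.  Helium points above
113 keV/μm and heavy-ion points above 155 keV/μm are excluded — measured
yields drop there (scoring losses from mitotic delay/interphase death at
high LET), and keeping them would underestimate high-LET damage.

`build_database()` tabulates linear-quadratic coefficients `Y(D) = αD +
βD²` on per-category LET grids (protons 2.5–30, He 5–110, heavy 5–150
keV/μm; default 2.5 keV/μm spacing) from curves simulated on 0–3 Gy — the
dose range of a single therapy fraction, where the LQ form is an adequate
description.  Lookups (`lookup_lq()`):

* Z = 0 → photon reference (Cs-137: α_X = 0.020 Gy⁻¹, β_X = 0.047 Gy⁻²);
* Z = 3 uses the helium entries, Z = 4, 5 the heavy entries (no dicentric
  data exist for Li/Be/B beams; category borrowing is the documented
  surrogate);
* linear interpolation in LET between grid nodes (the minimal continuous
  choice; the nearest-row alternative is not continuous and no published
  rule exists);
* above the last node the coefficients **plateau** at the last entry, and
  below the first node they clamp to the first entry — both deliberately
  conservative: overestimating healthy-tissue damage is preferred to
  underestimating it.

Negative fitted coefficients (possible on noisy low-yield curves) are
clipped to zero with a warning.

## Mixed-field RBE

For each voxel of a scored field, the Theory of Dual Radiation Action
motivates dose-weighted averaging over the particle components:
`ᾱ = Σ αᵢDᵢ / ΣDᵢ`, `β̄ = Σ βᵢDᵢ / ΣDᵢ`.  The voxel yield is closed as
`Y = ᾱD + β̄D²` (the TDRA-consistent choice), the photon-equivalent dose by
inverting the photon LQ,

```
D_X = (-α_X + sqrt(α_X² + 4 β_X Y)) / (2 β_X),
```

with the analytic limit `Y/α_X` when `β_X = 0` (removable singularity), and
`RBE = D_X / D`.  Zero-dose voxels are reported with `RBE = NA`: `D_X/D` is
undefined and a zero would poison downstream profiles.  Photon/electron
dose fractions (Z = 0 rows in scoring files) carry the photon reference
coefficients.  The radial scoring dimension is collapsed onto the beam axis
unless radial bins are requested, matching on-axis depth profiles.

## Synthetic data

Two generators replace external dependencies; neither claims physical
accuracy, and green tests built on them establish *software* correctness
(bookkeeping, averaging, inversion, recovery), not transport fidelity.

**SOBP scoring** (`make_sobp_scoring()`): 1 mm depth voxels over 0–200 mm;
a 5 cm SOBP (60–110 mm) at 1, 2 or 4 Gy uniform physical dose; entrance
channel at 55% of the SOBP dose rising toward the proximal edge; primary
carbon LET ramping 13 → 80 keV/μm quadratically toward the distal edge;
fragment species H/He/Li/Be/B with fixed relative weights and slowly rising
LETs; a 3% photon/electron fraction; an exponential fragment-only tail
(amplitude 15%, decay 25 mm) beyond the distal edge.  The per-voxel total
dose follows the analytic profile exactly; the seeded jitter (0.5%
lognormal) only reshuffles species fractions, which always sum to 1.  In
opposed mode the window is recentred on the midplane — the mirrored SOBPs
must coincide for the prescription to hold — and each beam delivers half
the dose, so healthy tissue sees entrance + tail mixtures, as in opposed
clinical fields.

**Pseudo-experiments** (`make_pseudo_experiment()`): dose-response curves
simulated at a known ground-truth CL yield with Poisson counting noise,
recording the truth in the file metadata for recovery tests.

**Packaged CL-yield defaults** (`default_cl_models()`): the source fits
behind the category models are not tabulated anywhere, so the packaged
coefficients are synthetic.  They were frozen from a one-off
magnitude-matching run: per category, lesion yields were solved (bisection
on the simulated 1 Gy dicentric yield, 4000 cells, fixed seed) to hit
typical published magnitudes — protons 0.03–0.12, He 0.10–0.35, heavy
0.15–0.40 dicentrics/cell at 1 Gy across each LET range — and the category
forms were then fitted with `fit_cl_vs_let()`.  They are illustrative
defaults, not claims about any reference implementation's internal values.

**Synthetic survival endpoint** (`synthetic_survival_db()`): a stand-in for
a chordoma cell-survival table used only for endpoint comparisons: photon
α_X = 0.159 Gy⁻¹ (the published chordoma photon value), α_X/β_X = 2 Gy, and
ion α rising linearly with LET (slope 0.055 per keV/μm, giving
chordoma-like SOBP RBEs of ~2–3).  With it, the pipeline reproduces the
clinically relevant qualitative behaviour: the low-α/β dicentric endpoint
shows the higher RBE-weighted dose in the low-dose fragmentation tail and
the lower one inside a 4 Gy SOBP.

## Numerical choices and edge cases

* **Fluence constant** 0.1602 Gy per (keV/μm)(μm⁻²): standard identity, so
  doses and LETs in conventional units need no further conversion.
* **Calibration search**: default bounds 0.05–2.5 CL/μm (generous around
  realistic yields); optimum on a bound raises a warning.  An all-zero
  observed curve drives the optimizer to the lower bound, flagged.
* **Sibling-only candidates**: an end whose only remaining partner is its
  sibling becomes permanently free regardless of `c_free`; likewise when
  all pair weights underflow to zero (e.g. `r0 → 0`).
* **Ties/degeneracy**: `fit_lq()` refuses curves without two distinct
  nonzero doses; database files are validated on read (header, photon row,
  strictly increasing per-category grids, non-negative coefficients) with
  the offending line reported.
* **Determinism**: every stochastic entry point takes a seed; database
  builds derive a stable per-entry sub-seed so entries are independent of
  grid order, and identical configuration + seed reproduces output files
  byte for byte.

## Known limitations

* No track-structure physics, no chromatin motion, no cell-cycle or
  mitotic-delay modelling, no complex-exchange saturation: at high doses
  and high LET the simulated yields can exceed saturating measured data.
* Nuclear architecture is schematic (content weighting or random Voronoi
  territories); territory shape effects on inter-chromosome distances are
  not modelled.
* The SOBP generator is parametric, not a transport calculation: fragment
  spectra, LET ramps and tail shapes are invented stand-ins, and RBE
  profiles computed on them demonstrate the engine, not a clinical beam.
* Calibration quality is bounded by Monte Carlo noise (`1/√n_cells`); the
  packaged acceptance tests recover truths within 10% at 2000 cells/dose.
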