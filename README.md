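# dicentra

Monte Carlo simulation of radiation-induced **dicentric chromosome
aberrations** in human peripheral blood lymphocytes, and per-voxel
**relative biological effectiveness (RBE)** for mixed particle fields along
therapeutic ion beams.

Dicentrics in circulating lymphocytes are a standard biomarker of
hematologic toxicity and late healthy-tissue damage after radiotherapy.
`dicentra` provides the full chain needed to predict them for ion beams:

1. **Aberration Monte Carlo** (`simulate_dose_response()`): ionizing
   radiation deposits *critical lesions* (CLs) — chromatin breaks that split
   a chromosome into independent fragments — along straight ion tracks
   (Poisson in number, with fluence Φ = D / (0.1602·LET)) or uniformly in
   the nucleus for photons.  Fragment free ends rejoin pairwise with a
   distance-dependent probability weight P(r) = exp(−r/r₀), r₀ = 0.8 μm for
   lymphocytes, or stay unrejoined; the junction graph is classified into
   dicentrics, centric rings and visible deletions.
2. **Calibration** (`calibrate_cl_yield()`, `fit_cl_vs_let()`): the CL
   yield (CL/μm of track) is the model's only adjustable parameter.  It is
   fitted per ion and LET against dose–response curves, and its LET
   dependence is fitted per category — linear-quadratic through the origin
   for protons and heavy ions (Z ≥ 4), linear for helium — excluding He
   points above 113 keV/μm and heavy-ion points above 155 keV/μm.
3. **Radiobiological database** (`build_database()`, `lookup_lq()`):
   simulated curves Y(D) = αD + βD² are fitted and tabulated per category
   and LET (protons 2.5–30, He 5–110, heavy 5–150 keV/μm) together with the
   Cs-137 photon reference α_X = 0.020 Gy⁻¹, β_X = 0.047 Gy⁻².  Lookups
   interpolate linearly in LET, map Li → He and Be, B → heavy, and plateau
   at the last grid entry above it (conservative high-LET rule).
4. **Mixed-field RBE engine** (`rbe_profile()`): per voxel, dose-weighted
   mean coefficients ᾱ = Σαᵢδᵢ/Σδᵢ, β̄ = Σβᵢδᵢ/Σδᵢ (Theory of Dual
   Radiation Action), yield Y = ᾱD + β̄D², photon-equivalent dose
   D_X = (−α_X + √(α_X² + 4β_X·Y)) / (2β_X), and RBE = D_X/D.
5. **Synthetic generators** (`make_sobp_scoring()`,
   `make_pseudo_experiment()`): a parametric spread-out-Bragg-peak scoring
   generator standing in for transport-code output, and pseudo-experimental
   curves with known ground truth for calibration tests.

## Worked example

```r
library(dicentra)

# dicentric dose-response for 60 keV/um He ions at 0.18 CL/um
dr <- simulate_dose_response(radiation_field("helium", 60),
                             cl_yield = 0.18, doses = c(0.5, 1, 2, 3),
                             n_cells = 2000, seed = 1)
dr
#>   dose_Gy mean_dicentrics      stderr n_cells mean_dic_rings
#> 1     0.5          0.1125 0.007807199    2000         0.1140
#> 2     1.0          0.2765 0.011920357    2000         0.2810
#> 3     2.0          0.6775 0.017829914    2000         0.6830
#> 4     3.0          1.0925 0.022208523    2000         1.1035

fit_lq(dr)       # linear-quadratic coefficients of that curve
#>      alpha       beta 
#> 0.22474536 0.04880927

# end to end: synthetic 5 cm SOBP at 4 Gy -> database -> RBE profile
db <- build_database(default_cl_models(),
                     grids = list(heavy = c(5, 40, 80, 150),
                                  helium = c(5, 40, 110),
                                  proton = c(2.5, 15, 30)),
                     n_cells = 400, seed = 1)
scor <- make_sobp_scoring(sobp_spec(dose_gy = 4), seed = 2)
prof <- rbe_profile(scor, db, endpoint2 = synthetic_survival_db(),
                    endpoint_names = c("dicentrics", "survival"))
subset(prof, depth_mm %in% c(85.5, 130.5) & endpoint == "dicentrics",
       c(depth_mm, dose_Gy, RBE, RBE_weighted_dose_Gy))
#>     depth_mm  dose_Gy      RBE RBE_weighted_dose_Gy
#> 86      85.5 4.000000 1.340309            5.3612355
#> 131    130.5 0.264259 2.271740            0.6003278
```

At 85.5 mm (inside the SOBP, 4 Gy) the dicentric RBE-weighted dose is
~5.4 Gy; at 130.5 mm (fragmentation tail, 0.26 Gy absorbed) the RBE is
higher (~2.3) although the absorbed dose is 15× lower — the low-dose,
low-α/β dicentric endpoint amplifies tail damage relative to a cell-survival
endpoint, which is the clinically relevant observation this pipeline
reproduces.

## Command line

```sh
Rscript -e 'dicentra::main()' make-sobp --dose 2 --opposed --out scoring.tsv --seed 7
Rscript -e 'dicentra::main()' build-db --cells 400 --seed 1 --out db.tsv
Rscript -e 'dicentra::main()' rbe --scoring scoring.tsv --db db.tsv --out profile.tsv
```

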