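# soilCA

Soil carbonic anhydrase (CA) activity from COS and CO¹⁸O trace-gas
exchange.

Soil microbes express carbonic anhydrases that hydrolyze carbonyl
sulfide (COS + H₂O → CO₂ + H₂S) and catalyze CO₂ hydration, during
which CO₂ exchanges oxygen isotopes with soil water
(CO₂ + H₂¹⁸O ⇌ CO¹⁸O + H₂O). Both gases are atmospheric tracers for
partitioning the land carbon flux into photosynthesis and respiration,
and the soil contribution to their budgets hinges on soil CA activity.
`soilCA` is for biogeochemists running flow-through chamber incubations
who want to turn concentration time series into enzyme kinetic
parameters, and for microbial ecologists relating those parameters to
community data.

The package implements:

- **Chamber fluxes** — phase-resolved series (inlet / N₂ zero / outlet)
  to net exchange rates, `F = (u/S)(c_o − c_i)`, with zero-offset
  subtraction, flushing discard and water-vapour dilution correction;
  partition of net COS exchange into abiotic production (dry-soil
  proxy) and enzymatic consumption.
- **Isotope processing** — the equilibrated fraction of through-flowing
  CO₂,
  `f_eq = (C_o δ_o − C_i δ_i − (C_o − C_i) δ_eq) / (C_i (δ_eq − δ_i))`,
  with the respired-CO₂ correction, jar-convergence gating and
  VSMOW/VPDB-CO₂ scale conversions.
- **Kinetics inversion** — a steady-state production–diffusion–reaction
  model of the soil column,
  `D_eff C″ = κBθC − P`, solved analytically
  (`F = PL·tanh(x)/x − C_a √(D_eff κBθ)·tanh(x)`, `x = L√(κBθ/D_eff)`)
  and inverted by bracketed root finding for the total rate constant κ;
  the CA-catalyzed rate `k_cat = κ − k_uncat(T, pH)`, enhancement
  factor `f_CA = k_cat/k_uncat` and substrate ratio `k_COS/k_CO2`
  follow, per replicate and aggregated by biome.
- **Community screens** — rarefaction, observed-OTU and Shannon
  diversity, the Spearman OTU screen (|ρ| > 0.5, Benjamini–Hochberg
  q < 0.01), transcripts-per-million normalisation and CA class/clade
  expression–rate Pearson correlations.
- **A synthetic-data generator** — every pipeline input with known
  ground truth (biome presets, chamber setpoints of ~450 ppt COS and
  ~450 ppm CO₂ at 0.3 L min⁻¹ and 20 °C, ¹⁸O-labelled soil water,
  planted taxa–rate and transcript–rate links), so the whole chain is
  testable end to end.

See `vignettes/soil-ca-activity.Rmd` for the model derivations,
parameter choices and limitations.

## Worked example

Simulate a 20-site triplicate study and run the full pipeline:

```r
library(soilCA)
study <- simulate_study(seed = 42)
run <- study$moist$runs[["site_01.1"]]
run
#> chamber_run: 720 samples, 0.30 L min^-1, 0.0078 m^2, 293.1 K

chamber_fluxes(run)
#>   F_cos_pmol   F_cos_se F_co2_umol    F_co2_se F_h2o_mmol     F_h2o_se n_cycles
#> 1  -2.472745 0.01337907   1.890068 0.001364079 0.05349982 0.0001337652        3
```

The moist tropical-grassland soil takes up COS at 2.47 pmol m⁻² s⁻¹
net (negative = uptake) while respiring 1.89 µmol m⁻² s⁻¹ of CO₂. The
dry-soil run of the same replicate emits COS, and that emission is the
production proxy used to isolate enzymatic consumption:

```r
dryF <- chamber_fluxes(study$dry$runs[["site_01.1"]])$F_cos_pmol
partition_cos(chamber_fluxes(run)$F_cos_pmol, dryF)
#>   production consumption flagged
#> 1   2.200722   -4.673468   FALSE
```

Inverting the column model for every replicate and aggregating:

```r
res <- run_pipeline(seed = 42, study = study)
res$rates[1, c("site", "biome", "k_cos_cat", "k_co2_cat")]
#>      site              biome k_cos_cat k_co2_cat
#> 1 site_01 tropical_grassland 0.5398939  0.635724

s <- res$biome_summary
print(s[match(c("tropical_grassland", "desert", "agricultural"), s$biome),
        c("biome", "n", "k_cos_cat_mean", "k_co2_cat_mean", "ratio_mean",
          "f_ca_cos_mean")], digits = 3)
#>                biome  n k_cos_cat_mean k_co2_cat_mean ratio_mean f_ca_cos_mean
#> 7 tropical_grassland  3          0.540          0.640      0.844         44800
#> 3             desert  6          0.185          0.580      0.286          1330
#> 1       agricultural 15          0.100          0.296      0.390          8083
```

Despite 5 ppt COS / 0.5 ppm CO₂ / 0.1 ‰ measurement noise, the
inversion recovers the planted tropical-grassland truth
(k_COS = 0.54 s⁻¹, k_CO2 = 0.64 s⁻¹, ratio 0.84) to three figures; the
enhancement factor of ~4.5 × 10⁴ over the uncatalyzed hydrolysis rate
(1.2 × 10⁻⁵ s⁻¹ at 20 °C, pH 7) is what makes net COS uptake a usable
enzyme assay. `res$screens` and `res$tpm_correlations` hold the OTU
hits (planted fungal lineages for k_COS) and the CA class/clade
expression correlations (β-clade-D with k_COS, α with k_CO2).

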