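# nanoblock

Single-molecule nanopore analysis for peptide sensing with
alpha-hemolysin (alpha-HL): simulation and idealization of voltage-clamp
current traces with peptide blockade events, two-substate fractional
blockade analysis, exponential dwell-time kinetics with voltage-dependence
fitting, and a quasi-1D excluded-volume conductance model of the pore.

## The problem

In resistive-pulse sensing, a single alpha-HL pore in a lipid bilayer
carries an ionic current I_open under a clamped transmembrane voltage dV.
Each reversible capture of a peptide blocks the pore transiently; for
engineered macro-dipole peptides (a neutral middle segment of six serines
or six isoleucines flanked by R12 and E12 charged tails) the in-event
current alternates between a deep substate I1 — a residue triplet centred
on the pore constriction — and a shallower substate I2 — the triplet
shifted off it. The analysis chain this package implements:

* **Fractional blockades** ΔI_block/I_open = |I_blocked − I_open|/I_open
  from pooled amplitude histograms, which discriminate serine
  (ΔI_block,1/I_open ≈ 0.91) from isoleucine (≈ 0.93) middle segments.
* **Kinetics**: waiting times τ_on and residence times τ_off are
  exponential; k_on = 1/(τ_on·C), k_off = 1/τ_off, with exact chi-square
  confidence intervals, and the capture rate follows
  k_on(dV) = k_on(0)·exp(a·dV), fitted log-linearly across a voltage
  ladder. Rate orderings across the four side/polarity conditions are
  evaluated with `check_orderings()`.
* **Pore model**: with the quasi-1D approximation E_z·A(z) = const, the
  pore resistance is R = (1/σ)∫dz/A(z); removing the excluded volume of a
  residue triplet from the constriction (Ile 175.4 Å³, Ser 100.7 Å³ per
  residue) predicts the blockade ordering between the two peptides.
  `area_profile_from_coords()` computes A(z) from PDB coordinates by slab
  rasterization and flood fill; `debye_length()` gives the electrolyte
  screening length.

Everything is tidyverse-native: traces and event tables are tibbles,
fitted objects have `tidy()`/`glance()` methods, and every result type has
an `autoplot()`.

## Worked example

Simulate a 30 s serine-peptide recording at +100 mV (capture rate 10/s at
30 µM, k_off 50/s, depths 0.91/0.83, 2 pA noise, 50 kHz), then recover
everything back:

```r
library(nanoblock)

model <- gating_model(
  k_on_0 = 10 / 3e-5, a = 0, concentration = 3e-5, k_off_0 = 50,
  i_open = 100, frac_block_1 = 0.91, frac_block_2 = 0.83, noise_sd = 2
)
config <- acquisition_config(sampling_rate = 5e4, filter_cutoff = 1e4,
                             voltage = 100, duration = 30, seed = 11)

trace  <- simulate_trace(model, config)
events <- detect_events(trace)
nrow(events)
#> [1] 253

amplitude_histogram(events, trace)
#> <blockade_stats> i_open = 100.05 pA; I1 = 9.04 pA (frac 0.910); I2 = 16.94 pA (frac 0.831)

compute_kon(exp_mle(event_intervals(events)), concentration = 3e-5)
#> <rate_estimate> k_on = 3.433e+05 1/(M s) (CI 3.022e+05-3.869e+05, n = 252)
compute_koff(exp_mle(event_durations(events)))
#> <rate_estimate> k_off = 48.18 1/s (CI 42.43-54.3, n = 253)
```

The recovered deep and shallow fractional blockades (0.910, 0.831) match
the generating depths to three decimals, and both generating rate
constants (k_on = 3.33e5 M⁻¹s⁻¹, k_off = 50 s⁻¹) fall inside their 95%
confidence intervals.

The excluded-volume model ranks the bulkier isoleucine triplet above the
serine triplet on the same geometry:

```r
geom <- parametric_alpha_hl()
predict_blockade(geom, peptide_model("Pe4"))$frac_block  # isoleucine
#> [1] 0.1710955
predict_blockade(geom, peptide_model("Pe6"))$frac_block  # serine
#> [1] 0.07163467
debye_length(2, 1, 300, 70)  # Angstrom, 2 M KCl
#> [1] 2.037557
```

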