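---
title: "Methods: simulating and analysing peptide blockades of alpha-hemolysin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing peptide blockades of alpha-hemolysin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoblock)
```

# The measurement this package models

In resistive-pulse sensing a single alpha-hemolysin (alpha-HL) pore sits in
a lipid bilayer between two electrolyte chambers (*cis*, grounded, and
*trans*) under a clamped transmembrane voltage. Each reversible capture of
a peptide produces a transient reduction of the ionic current; the depth,
duration and frequency of these blockades carry information about the
peptide. For engineered macro-dipole peptides — a neutral middle segment of
six serines or six isoleucines flanked by R~12~ (+12 e) and E~12~ (−12 e)
tails — the current during a single capture alternates between two
sub-levels: a deep state $I_1$ (a residue triplet centred on the pore
constriction) and a shallower state $I_2$ (the triplet shifted partly off
the constriction).

The package provides four coordinated pieces:

1. a **trace simulator** with the statistical structure this analysis
   assumes,
2. an **event detector and idealizer** (baseline, hysteresis thresholds,
   substate segmentation, pooled amplitude histograms),
3. **dwell-time kinetics** (exponential MLE with exact confidence
   intervals, $k_{on}$/$k_{off}$, the exponential voltage model), and
4. a **quasi-1D excluded-volume conductance model** of the pore.

# The stochastic trace model

Captures arrive as a Poisson process with rate $k_{on}(\Delta V)\,C$, where
$C$ is the bulk peptide concentration and

$$k_{on}(\Delta V) = k_{on}(0)\, e^{a \Delta V},$$

residence times are exponential with rate $k_{off}(\Delta V) =
k_{off}(0)\,e^{b\Delta V}$, and within an event the level alternates
between $I_1$ and $I_2$ as a two-state continuous-time Markov chain.
Because one pore holds one peptide, events are generated sequentially:
the waiting time $\tau_{on}$ is the gap between an event's end and the next
capture. An event still open at the end of the record is truncated and
flagged `censored`; censored durations are excluded from dwell-time fits so
the exponential MLE stays unbiased.

Rendering maps substate $k$ to the level $I_{open}(1 - f_k)$ with
fractional blockades $f_1 > f_2$, emulates the acquisition low-pass filter
by Gaussian smoothing of the noiseless square signal (kernel sd
$0.1325\, f_s/f_c$ samples, the −3 dB equivalent), and then adds i.i.d.
Gaussian noise. Adding broadband noise *after* the filter keeps `noise_sd`
interpretable as the baseline sample standard deviation; `filter_noise =
TRUE` filters the noise too. Currents are stored as positive magnitudes in
pA; the sign of $\Delta V$ lives in the metadata.

## Default study conditions

| parameter | default | why |
|---|---|---|
| sampling rate | 50 kHz | standard acquisition rate for this setup |
| filter cutoff | 10 kHz | standard low-pass for single-channel records |
| $I_{open}$ | 100 pA | representative open-pore current at 2 M KCl, +100 mV |
| noise sd | 2 pA | typical baseline noise after a 10 kHz filter |
| $f_1,\ f_2$ | 0.91, 0.83 | deep/shallow depths of the serine peptide |
| concentration | 30 µM | working peptide concentration for voltage series |
| substate switching | 500 s⁻¹ each way | free parameter, see below |
| $a$ | 0.02 mV⁻¹ | free parameter, see below |

Two of these are **free parameters of the simulator, not measured
quantities**. The intra-event switching rates between $I_1$ and $I_2$ are
not experimentally constrained; 500 s⁻¹ each way gives 2 ms mean dwells
(about 100 samples at 50 kHz), long enough that both histogram peaks are
well resolved yet short enough that a typical 20 ms event visits both
substates many times. The voltage-sensitivity exponent $|a| = 0.02$ mV⁻¹
is a representative magnitude for voltage-assisted capture in this system;
recovery tests and the acceptance script state it explicitly wherever it is
used, and its sign follows the polarity of the clamped voltages. Both were
fixed once, before any recovery checks were run.

The generator emulates Poisson arrivals, exponential dwells, two-level
substate switching, Gaussian noise and the filter rise time. It does *not*
emulate 1/f (flicker) noise, baseline drift, electrode offset, capacitive
transients, or electroosmotic flow (sidedness and polarity enter only
through the per-condition value of $k_{on}(0)$ the user sets). Passing
recovery tests on this generator therefore demonstrates correctness of the
estimators under the stated statistical model, not robustness to every
artefact of bench recordings.

# Event detection and idealization

The open-pore level is the mode of the amplitude distribution (highest
peak of a kernel-smoothed histogram) — robust here because blockades are
deep (≥ 80%) and occupancy moderate; the noise is the scaled MAD of
samples within 3 initial MADs of that level. Detection uses hysteresis:
an event opens below $0.7\,I_{open}$ and closes above $0.9\,I_{open}$.
Mid-range thresholds separate states robustly at 2 pA noise because the
blocked levels sit at 7–17 pA; because both thresholds are fractions of
the estimated baseline, detection is invariant to rescaling the trace.
Events shorter than 100 µs (five samples) are discarded to respect the
10 kHz filter rise time; events touching the record boundaries are flagged
censored; the two samples nearest each boundary are excluded from
amplitude means (a partially smeared sample can survive at the exit edge,
so noise-free square-wave amplitudes are exact only to about $10^{-3}$ pA).

$\tau_{on}$ is defined as the gap between an event's end and the next
event's start; the leading gap is discarded as left-censored.

Substate segmentation assigns each in-event sample to the nearer of the
two level guesses and merges runs shorter than 100 µs into their longer
neighbour — deliberately simple (no HMM), adequate at the depth separation
and dwell lengths of this system. Reported $I_1$/$I_2$ come from the
*pooled* amplitude histogram across events (bin width
$\max(\text{noise sd}/2,\ 0.1\text{ pA})$, 3-bin moving-average smoothing,
two highest local maxima at least 3 bins apart, ties toward the
lower-current bin), with quadratic three-point interpolation so peak
positions are not quantized to the bin grid. Fractional blockades are
$|I_{blocked} - I_{open}|/I_{open}$, reported as positive magnitudes.

# Dwell-time kinetics

For exponential dwells the MLE of the mean is the sample mean, and
$2n\hat\tau/\tau \sim \chi^2_{2n}$ gives the exact interval
$[2n\hat\tau/q_{1-\alpha/2},\ 2n\hat\tau/q_{\alpha/2}]$. This standard
exact construction is used throughout (coverage is verified by simulation
in the test suite). Rates follow as $k_{on} = 1/(\hat\tau_{on} C)$ and
$k_{off} = 1/\hat\tau_{off}$, with CI endpoints transformed monotonically.
Concentration always comes from the dataset's metadata — different
experiments use different peptide concentrations, so no global constant is
assumed.

The voltage model is fitted as $\ln k = \ln k_0 + a\Delta V$ by unweighted
least squares (optionally inverse-variance weighted, or a direct `nls` fit
behind a flag; the log-linear form is numerically stable and equivalent at
the attainable precision, and `nls` fails on exactly-collinear input, which
is another reason it is not the default). $k_{off}$ is reported
per voltage without a functional fit: no exponential law is claimed for
dissociation, and the simulator's `b` parameter defaults to zero.
`check_orderings()` evaluates the expected inequality chains over the four
side/polarity conditions, either on $k_0$ (near equilibrium) or on
$k(\pm 140\text{ mV})$ (high voltage).

Censored events are excluded rather than Kaplan–Meier corrected; at the
event counts used here (hundreds per condition) at most one event per
trace is censored, a negligible bias for a large saving in machinery.

# The quasi-1D pore model

Treating the pore and membrane as insulators, the electric-field flux
$E_z A(z)$ is constant along the pore, so axial slices act as resistors in
series:

$$R = \frac{1}{\sigma}\int \frac{dz}{A(z)},$$

with $A(z)$ the electrolyte-accessible cross-section and $\sigma$ the bulk
conductivity. $1/A(z)$ is the local resistivity indicator: largest in the
constriction, intermediate in the β-barrel, negligible in the vestibule.
Access (convergence) resistance at the pore mouths is deliberately
omitted — the model is intra-pore only, used for *relative* blockade
predictions in which the access term would largely cancel.

The parametric geometry is piecewise cylindrical in z ∈ [0, 100] Å (z = 0
at the trans barrel mouth): barrel radius 10 Å on [0, 44], a constriction
on [44, 50] whose area is set so the region volume is 924 Å³ (radius
≈ 7.0 Å), vestibule radius 23 Å on [50, 100], with 2 Å linear area tapers
at the junctions (a discontinuous step would make the trapezoidal
integral grid-sensitive). Conductivity defaults to 20 S/m, representative
of 2 M KCl at room temperature; it scales absolute currents only, never
fractional blockades, and no validated quantity depends on it.

`area_profile_from_coords()` computes $A(z)$ from atomic coordinates
(PDB via bio3d, van der Waals radii by element, probe radius 1.4 Å): each
z-slab is rasterized in xy, cells within (atom radius + probe) of an atom
whose z lies within half a slab of the slice are excluded, and the open
area is counted by a 4-neighbour flood fill seeded on the pore axis, which
discards the exterior and disconnected voids. On analytic cylinder and
annulus fixtures the error is bounded by one grid-cell ring of the
boundary and shrinks with the cell size. Pseudo-atom fixtures are built so
the *dilated* wall surface lies exactly at the target radius.

The excluded-volume blockade model removes $n \times V_{res}$ (three
residues by default; Ile 175.4 Å³, Ser 100.7 Å³) from the constriction's
free volume as a uniform area decrement over its z-span (`centered`, the
deep state), or splits it between the constriction and an adjacent barrel
slab (`offset`, the shallow state). The fractional blockade is
$1 - R_{open}/R_{blocked}$. Uniform spreading is the minimal assumption
consistent with a volumetric model; the prediction is *ordinal* — it
ranks isoleucine above serine and centered above offset, and is strictly
increasing in excluded volume — but it does not reproduce the measured
0.91/0.93 depths, which would require the full atomistic area reduction
along the barrel, dehydration and charge effects outside this model's
scope.

## The Debye-length check

`debye_length()` evaluates
$\kappa^{-1} = \sqrt{\varepsilon_r\varepsilon_0 k_B T / (2 e^2 N_A
\cdot 1000\, I)}$ with ionic strength $I = \tfrac12\sum_i z_i^2 C_i$.
At 0.1 M, 298 K, $\varepsilon_r = 78.5$ it gives 9.6 Å, the textbook
value. At the conditions used for this system — 2 M KCl, 300 K,
$\varepsilon_r = 70$ — the closed form evaluates to **2.04 Å**, slightly
above the ~1.9 Å figure quoted for these conditions; 1.9 Å is not
reproducible from the formula at the stated inputs (it would need
$\varepsilon_r \approx 61$). The package reports the formula's value and
the test suite documents the ~0.14 Å discrepancy rather than adjusting
constants to match the quoted number. Either value supports the same
physical conclusion: screening is much shorter than the 20 Å barrel
diameter, so tail–wall electrostatics act only at sub-nanometre
separations.

# Numerical choices and degenerate inputs

* **Determinism.** Every stochastic function takes a single integer seed;
  a voltage series uses seed + (index − 1) per voltage; rendering draws
  noise from seed + 1. The same seed and configuration reproduce traces
  bit for bit and the pipeline summary byte for byte.
* **Degenerate inputs.** Constant traces give noise_sd 0; empty traces,
  empty dwell lists, non-positive rates or concentrations are errors;
  n < 5 dwells flags the CI low-n; events with < 3 samples get a single
  substate; a slab whose axis cell is blocked reports zero area with a
  warning, and any zero area makes the resistance infinite (explicitly,
  not by overflow).
* **Ties.** Histogram peak ties break toward the lower-current bin;
  substate-run merging prefers the longer neighbour.
* **Problem sizes.** Validation uses 30 s traces at 50 kHz (≈ 250 events,
  1.5 M samples) for blockade recovery, 1000 events per voltage across six
  voltages for rate-constant recovery, and 1000 replicates of n = 50 for
  CI coverage — sizes at which Monte-Carlo error is comfortably below the
  tolerances being checked while the whole suite runs in a few minutes.

# Known limitations

* No HMM idealization, at most two substates, no baseline-drift
  correction: adequate for deep, well-separated blockades, not for
  shallow or multi-level signals.
* Kinetics assume single-exponential dwells; mixtures are out of scope.
* The conductance model is quasi-1D and ohmic: no Poisson–Boltzmann
  electrostatics, no electroosmosis, no access resistance.
* Synthetic validation cannot certify behaviour on bench artefacts the
  generator does not emulate (drift, flicker noise, multi-pore insertions).
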