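---
title: "Modelling steady-state CDOM photochemistry in sunlit surface waters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling steady-state CDOM photochemistry in sunlit surface waters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdomphoto)
```

## The model

Chromophoric dissolved organic matter (CDOM) is the dominant UV–visible
absorber in freshwaters and a key photosensitiser: its excited triplet
states (³CDOM\*) and the species derived from them — singlet oxygen
(¹O₂), the hydroxyl radical (•OH) and, via carbonate oxidation, the
carbonate radical (CO₃•⁻) — drive the indirect photodegradation of many
contaminants. `cdomphoto` computes the steady-state concentrations of
these four transients in a well-mixed water column as a function of the
column depth, the water chemistry, and above all the CDOM *spectral
quality*.

**Optics.** CDOM column absorbance follows the exponential spectral-slope
model

$$A_\mathrm{CDOM}(\lambda) = 100\, d\, \mathrm{DOC}\, A_0\, e^{-S\lambda},$$

with depth $d$ (m), dissolved organic carbon DOC (mg~C~ L⁻¹), the
pre-exponential factor $A_0$ (L mg~C~⁻¹ cm⁻¹, chromophore density) and
the spectral slope $S$ (nm⁻¹, inversely related to CDOM molecular
weight). Nitrate and nitrite column absorbances are
$\varepsilon_i(\lambda) c_i \cdot 100 d$ from packaged molar-absorption
tables. All absorbances are decadic: the column absorbs the fraction
$1 - 10^{-A_\mathrm{tot}(\lambda)}$ of incident photons.

**Photon competition.** The three photosensitisers compete for the same
photons. Within the absorbed fraction, chromophore $i$ receives the
share $A_i(\lambda)/A_\mathrm{tot}(\lambda)$ (taken as 0 where
$A_\mathrm{tot}=0$), the standard well-mixed treatment. Absorbed photon
rates are wavelength integrals against the column-averaged spectral
photon flux density $p^\circ(\lambda)$ (Einstein L⁻¹ s⁻¹ nm⁻¹):

$$P_a^{(i)} = \int p^\circ(\lambda)\,
  \bigl[1 - 10^{-A_\mathrm{tot}(\lambda)}\bigr]\,
  \frac{A_i(\lambda)}{A_\mathrm{tot}(\lambda)}\, d\lambda .$$

This competition rule reproduces the screening behaviour central to the
science: raising CDOM absorbance strictly *decreases* the photons
available to nitrate and nitrite.

**Kinetics.** Formation rates are quantum yields applied to the absorbed
photon rates: $R_{^3\mathrm{CDOM}^*} = \Phi_{^3\mathrm{CDOM}^*}
P_a^{\mathrm{CDOM}}$;
$R_{\bullet\mathrm{OH}} = \Phi^{\mathrm{CDOM}}_{\bullet\mathrm{OH}}
P_a^{\mathrm{CDOM}} + \Phi^{\mathrm{NO_3}}_{\bullet\mathrm{OH}}
P_a^{\mathrm{NO_3}} + \Phi^{\mathrm{NO_2}}_{\bullet\mathrm{OH}}
P_a^{\mathrm{NO_2}}$ (the per-source terms give the •OH source
apportionment). Triplet CDOM in aerated water is quenched essentially
entirely by dissolved O₂, yielding ¹O₂ with fraction $f_\Delta$;
¹O₂ decays by collision with water. •OH is scavenged by DOM, inorganic
carbon, and nitrite; CO₃•⁻ forms from •OH + HCO₃⁻/CO₃²⁻ plus a secondary
³CDOM\* + CO₃²⁻ pathway, and is scavenged by DOM. Every transient is
closed with the steady-state approximation
$[X]_{ss} = R_X / \sum_j k_j$ — the sources-and-sinks picture the
science describes, never written as an equation there; it makes every
output analytic in the photon budgets, hence strictly linear in
$p^\circ$.

## Parameters that matter

The registry (`photo_params()`, printable with provenance via
`params_dump()`) holds literature-default effective values; the
underlying reference software does not publish its internal set, so
absolute concentrations carry that uncertainty (roughly a factor of 2),
while trends and sign structure are robust to it.

| entry | default | units | meaning |
|---|---|---|---|
| `phi_3CDOM` | 1.25e-3 | mol E⁻¹ | ³CDOM\* formation yield |
| `phi_OH_CDOM` | 3e-5 | mol E⁻¹ | •OH yield of CDOM |
| `phi_OH_NO3` | 1e-2 | mol E⁻¹ | •OH yield of nitrate |
| `phi_OH_NO2` | 2.5e-2 | mol E⁻¹ | •OH yield of nitrite |
| `f_delta` | 0.5 | — | ¹O₂ yield of ³CDOM\* + O₂ |
| `k_q3` | 5e5 | s⁻¹ | O₂ quenching of ³CDOM\* |
| `k_d1O2` | 2.5e5 | s⁻¹ | ¹O₂ decay by water |
| `k_OH_DOM` | 5e4 | L mg~C~⁻¹ s⁻¹ | •OH + DOM |
| `k_OH_HCO3` | 8.5e6 | M⁻¹ s⁻¹ | •OH + HCO₃⁻ |
| `k_OH_CO3` | 3.9e8 | M⁻¹ s⁻¹ | •OH + CO₃²⁻ |
| `k_OH_NO2` | 1e10 | M⁻¹ s⁻¹ | •OH + NO₂⁻ |
| `k_CO3_DOM` | 1e2 | L mg~C~⁻¹ s⁻¹ | CO₃•⁻ + DOM |
| `k_3CDOM_CO3` | 1e5 | M⁻¹ s⁻¹ | ³CDOM\* + CO₃²⁻ |

Two structural identities follow from the defaults: `k_q3 = 2 * k_d1O2`
(triplet quenching about twice as fast as singlet-oxygen decay) together
with `f_delta = 0.5` makes $[{}^1O_2]_{ss} = [{}^3CDOM^*]_{ss}$ exactly,
so every triplet result doubles as a singlet-oxygen result. Quantum
yields are wavelength-independent effective values; nitrite scavenging
of •OH is included because at 10⁻⁵ M nitrite its term (≈10⁵ s⁻¹) rivals
DOM scavenging and omitting it would silently distort the high-nitrite
regime.

## The solar field

The packaged spectrum (`inst/extdata/solar_spectrum_synthetic.txt`) is a
*synthetic* clear-sky surface irradiance: a 5778 K solar blackbody
attenuated by Rayleigh scattering, aerosol extinction, and ozone
absorption at airmass 1.41 (mid-latitude equinox noon), with a crude
diffuse-recovery term; no standard tabulation could be redistributed
here. Its absolute scale is irrelevant: at load time the spectrum is
renormalised so that the 290–400 nm band integrates to exactly
22 W m⁻², the fair-weather UV irradiance the model fixes. Only the
residual *shape* matters, and it is the single largest source of
uncertainty in absolute outputs (it also decides near-ties such as the
exact grid position of the •OH-vs-S minimum, which lands one 0.001 nm⁻¹
step right of centre here).

The default wavelength grid is 290–800 nm at 1 nm. The lower edge is
where surface sunlight begins. For the upper edge, the formation-rate
integral has no natural cutoff: with central parameters
$A_\mathrm{CDOM}(500) \approx 0.37$, i.e. a 3 m column still absorbs
over half the photons at 500 nm, and the low-$S$/high-$S$ contrast that
produces the studied dynamic range of $[{}^3CDOM^*]$ lives largely in
this visible tail. Truncating at 500 nm (a tempting choice, since CDOM
*dominance over other absorbers* is only asserted below 500 nm)
compresses the spectral-sweep range by more than half and is therefore
rejected; between 500 and 800 nm CDOM is treated as the only absorber,
which is consistent with the competition structure (nitrate and nitrite
do not absorb there).

Conversions are exact bookkeeping: photon flux is
$E(\lambda)\lambda/(h c N_A)$ per nm, and the column-averaged
volumetric flux divides by the column volume $1000\,d$ litres per m².
All integrals are trapezoidal; on these smooth integrands refining the
grid from 1 nm to 0.1 nm moves photon budgets by ≈0.1% (tested).

## Scenarios, presets and the random generator

`preset_scenario()` fixes the studied water: 3 m depth, DOC 5 mg~C~ L⁻¹,
10⁻³ M HCO₃⁻, 10⁻⁵ M CO₃²⁻, central CDOM (0.45, 0.015), and three
nitrate/nitrite regimes — intermediate (10⁻⁴/10⁻⁶ M; `fig2`, `fig4`,
`central`), nitrogen-poor (10⁻⁶/10⁻⁸ M; `fig5`, e.g. hypertrophic lakes
where algae strip inorganic nitrogen) and nitrogen-rich (10⁻³/10⁻⁵ M;
`fig6`, near drinking-water limits).

`sample_scenarios()` draws random but environmentally plausible waters:
$A_0 \in [0.30, 0.60]$, $S \in [0.012, 0.018]$ and depth (0.5–10 m,
typical well-lit epilimnia) uniformly; DOC (0.5–50 mg~C~ L⁻¹) and all
molar concentrations log-uniformly, because they span orders of
magnitude — mirroring how the sensitivity analyses vary them. Nitrate
and nitrite bounds span the three studied regimes; carbonate bounds
bracket common freshwater alkalinity. Seeds are mandatory and the global
RNG state is left untouched. The generator emulates *ranges*, not joint
field correlations (e.g. DOC–alkalinity covariance in real surveys), so
a green property test establishes behaviour across the plausible box,
not distributional realism.

## Sensitivity analyses

* `spectral_grid_sweep()` — the 7 × 7 matrix $A_0 = 0.30\ldots0.60$
  (step 0.05) × $S = 0.012\ldots0.018$ (step 0.001) around the central
  freshwater point; deterministic row order (A₀ outer, S inner).
* `doc_sweep()` — 24 log-spaced DOC values over 0.5–50 mg~C~ L⁻¹ at
  fixed (0.45, 0.015).
* `match_equivalent_doc()` — expresses a change in CDOM *quality* as the
  equivalent change in *quantity*: bisection on $\log_{10}\mathrm{DOC}$
  over [10⁻², 10³] mg~C~ L⁻¹ (relative tolerance 10⁻³), legitimate
  because the triplet concentration is strictly increasing in DOC. Near
  the total-absorption plateau the inverse is ill-conditioned (a tiny
  concentration error moves DOC a lot), so the high-DOC equivalence is
  asserted as a plateau ratio, not by root-finding.
* `locate_extremum()` — grid argmin of a value-versus-$S$ series, ties
  toward smaller $S$, no sub-grid interpolation: 0.001 nm⁻¹ is the
  model's stated resolution and interpolating below it would claim
  precision the inputs do not have.

## Numerical choices and degenerate inputs

Decadic absorbance throughout (never natural-log); the branching ratio
$A_i/A_\mathrm{tot}$ is defined as 0 where nothing absorbs; a zero
formation rate yields a zero steady state regardless of sinks, while a
positive rate with zero sink raises an error (no steady state exists);
•OH source fractions are `NA` when there is no •OH production. Sweep
CSVs are written in 6-significant-digit scientific notation with a `#`
metadata header (sweep kind, preset, parameter-registry md5, spectrum
source); scenario batches are written at full double precision so they
round-trip exactly.

## Known limitations

Absolute concentrations inherit the spectrum-shape and quantum-yield
uncertainty above (factor ≈2); trends, monotonicities and regime
reversals are the robust outputs. No radiative transfer or
depth-resolved light field (column-averaged by construction), no
seasonal or diurnal variation, no temperature dependence, no
wavelength-dependent quantum yields, and no pollutant-specific
degradation kinetics — the model stops at the reactive intermediates
themselves.
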