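---
title: "An individual-based model of antibiotic response in two-lineage biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of antibiotic response in two-lineage biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmr)
```

## The model

`biofilmr` simulates a surface-attached microbial community of two lineages —
an antibiotic-resistant type R and a susceptible type S — as individual disks
on a 2D domain of unit depth. Cells sense the solute concentrations of the
voxel they sit in, grow by Monod kinetics, divide when they reach a division
radius, and mechanically shove their neighbours apart. Solutes (nutrients,
metabolic by-products, antimicrobial toxins, and a bacteriostatic antibiotic)
diffuse from a well-mixed bulk compartment above the biofilm and react with
the biomass; their fields are held at *pseudo-steady state*: diffusion
equilibrates much faster than biomass changes, so after every biomass step
the stationary reaction–diffusion problem

$$0 \;=\; D\,\nabla^2 C_s \;+\; q_s(\mathbf{C}, X_R, X_S)$$

is re-solved for every solute $s$, warm-started from the previous fields.

Growth of a lineage follows one or two reaction routes of the form

$$\mu \;=\; \mu_{max}\;\prod_m \frac{C_m}{C_m + K_m}\;\prod_i \frac{K_{i}}{C_i + K_{i}},$$

a product of Monod saturation factors over the consumed substrates and
hyperbolic inhibition factors over toxins and antibiotic. Each route carries a
stoichiometry in grams of solute per gram of biomass formed: substrate
consumption at $-1/Y$, by-product and toxin release at $+1$, and antibiotic
removal at $-\alpha$ on every R route (growth-coupled detoxification — no
free enzyme is released, so there is no detoxification without growth). The
antibiotic is purely bacteriostatic: it scales S growth by
$K_{iA}/(A+K_{iA})$ but never kills, so cell counts and per-cell masses are
non-decreasing.

### The four media

The interaction between R and S is set entirely by the medium's reaction
network:

| medium | nutrients | coupling |
|---|---|---|
| `interference_competition` | shared `N` | each lineage releases a toxin inhibiting the other |
| `exploitation_competition` | shared `N` | competition through nutrient depletion only |
| `non_crossfeeding` | private `N_R`, `N_S` | no solute coupling (space competition only) |
| `crossfeeding` | private `N_R`, `N_S` | each lineage releases a by-product (`E_R`, `E_S`) the other can grow on |

All interactions are symmetric at baseline: with zero resistance cost, no
detoxification, and no antibiotic, swapping the R and S labels (together with
their private solutes) leaves every rate unchanged. Resistance may carry a
cost `cost_c`, an absolute reduction of $\mu_{max}$ in h⁻¹; because
$\mu_{max} = 1$ h⁻¹ by default this coincides with the fractional reading
(0.1 = a 10 % cost).

### Default parameters

Kinetics: $\mu_{max} = 1\,h^{-1}$, $K_N = K_E = 3.5\times10^{-5}$ g/L,
$Y_N = Y_E = 0.5$ g/g, $K_{iT} = K_{iA} = 0.1$ g/L. Environment: bulk
nutrient 0.05 g/L, bulk antibiotic 0, 0.05 ("low toxicity") or 0.2 ("high
toxicity") g/L; all solutes diffuse at $7.2\times10^{-6}$ m²/day
($3\times10^{5}$ µm²/h). By-products and toxins have bulk value 0: the bulk
is an absorbing sink for anything the biofilm secretes.

Two parameter choices deserve comment because they are genuinely open:

* **Private nutrient supply.** In the private-nutrient media the model needs
  bulk values for both `N_R` and `N_S` but only a single nutrient
  concentration (0.05 g/L) is canonical. We give *each* private nutrient the
  full 0.05 g/L: splitting a shared budget would break the symmetry between
  the shared-nutrient and private-nutrient media at the level of a single
  lineage's growth, and the qualitative contrasts between media are the
  object of study, not absolute yields.
* **Detoxification strength.** No canonical numeric value exists for
  $\alpha$; the detoxification suites default to $\alpha = 1$ g antibiotic
  per g biomass, exposed prominently as a sweep parameter.

### Cell geometry and division

Cells are disks of unit depth with fixed cytoplasm density
$\rho = 200$ g/L, so $m = \rho \pi r^2$. A cell divides at radius 1 µm
($m_{div} = 200\pi \approx 628$ fg) into daughters with mass fractions
$f$ and $1-f$, $f \sim U(0.45, 0.55)$ — the jitter breaks the artificial
symmetry of simultaneous divisions — placed at half the parent radius on
either side of the centre along a uniform random direction. Inocula start at
$m_{div}/2$ (fresh daughters). Both density and division radius are
configurable; the qualitative outcomes are insensitive to moderate (±50 %)
changes in $m_{div}$, which only rescale the count-per-biomass ratio.

### Numerics

* **Lattice.** Grid spacing $h = 2$ µm, x-periodic, no-flux substratum,
  Dirichlet bulk values from one boundary layer (default 40 µm) above the
  highest occupied voxel upward. Biomass is deposited whole-voxel: a voxel
  holds the summed mass of the cells whose centres it contains, divided by
  the voxel volume $h\times h\times 1$ µm³ (1 fg/µm³ ≡ 1 g/L), conserving
  mass exactly.
* **Pseudo-steady solve.** Damped Picard iteration over the coupled solutes:
  sources are linearised around the current concentrations — consumption that
  passes through a Monod factor on the solute itself goes on the diagonal,
  which keeps iterates non-negative — and relaxed with red–black SOR
  ($\omega = 1.8$, two sweeps per solute per outer cycle) until the joint
  relative field change is below $10^{-6}$. Antibiotic removal by R is
  independent of the local antibiotic concentration, so strong sinks can
  drive the linearised iterate negative; negative values are truncated to
  zero. In a truncated (fully depleted) region the pointwise residual cannot
  vanish — the depletion front is an obstacle-problem free boundary — which
  is why convergence is measured on the field change, not the raw residual.
  On problems without truncation the solver is independently verified against
  the closed-form cosh profile of a first-order-sink slab and against the
  discrete divergence theorem (influx = consumption).
* **Growth update.** $m \leftarrow m\,e^{\mu\,dt}$ with $\mu$ frozen over the
  step — exact under constant $\mu$, and with $dt = 0.02$ h and
  $\mu \le 1$ h⁻¹ the per-step mass change (≈2 %) stays well inside the
  pseudo-steady assumption.
* **Shoving.** Overlapping pairs are displaced apart symmetrically by half
  the overlap each, sweeping in ascending id order (reproducibility) until
  the largest overlap is below 0.01 µm or 5000 sweeps. Coincident centres
  are separated along a deterministic direction derived from the pair's ids.
* **Determinism.** All randomness flows through R's RNG from the config
  seed; the C++ kernels are deterministic, so a seed fixes the whole run
  byte-for-byte.
* **Sealed variant.** `simulation_config(sealed = TRUE)` replaces the
  spatial fields with well-mixed solute pools depleted stoichiometrically by
  the biomass actually formed — a closed-culture limit used to verify that
  growth and stoichiometry stay mass-consistent (biomass gained × 1/Y plus
  nutrient remaining equals the initial nutrient).

### Degenerate inputs and edge cases

Zero-duration runs return the inoculum snapshot (after one solute refresh);
a zero-dt step refreshes fields only. Cells never die, detach, or shrink;
starved cells persist at zero growth and can resume if nutrient returns.
The segregation index is reported as `NA` when undefined (single-species
populations, or focal cells with empty neighbourhoods — such cells are
dropped from the average rather than assigned 0 or 1, since either
assignment would bias the index at low density). The focal cell is excluded
from its own neighbourhood: self-inclusion would bias the local proportion
toward the focal type exactly where neighbourhoods are sparse.

## Metrics and outcome statistics

* **Census.** Counts, biomass, mean biofilm height (mean over columns of the
  highest occupied voxel).
* **Segregation index.** $s_R = (p_{local} - p_{global})/(1 - p_{global})$,
  where $p_{local}$ averages, over R cells, the proportion of R among the
  neighbours within a 10 µm radius (periodic in x). ≈0 for random mixing,
  ≈1 for full segregation, negative for over-dispersion. The implementation
  is tested for exact agreement with a brute-force double loop.
* **Ecological outcome.** $R_{co} - R_{mono}$ and $S_{co} - S_{mono}$ at a
  common time: both positive = mutualists, both negative = competitors,
  mixed = exploitation.
* **Antibiotic response.** Release statistic
  $R_{co}[A>0] - R_{co}[A=0]$ (positive: competitive release; negative:
  mutualistic suppression) and cross-protection statistic
  $S_{co}[A>0] - S_{mono}[A>0]$ (positive: cross-species phenotypic
  resistance). All outcome statistics are computed on cell counts; biomass
  columns are carried alongside.

## Experiment scales

The canonical design seeds 120 cells per lineage on a 258 µm domain and runs
36 h with 3 replicates. The package's suites default to a *reduced* design —
130 µm domain, 40 cells per lineage, 24 h, 2 replicates — which preserves
the full design structure and the sign structure of the headline outcomes
while one design cell (coculture + both monocultures at one antibiotic
level) completes in well under a minute; a *mini* scale (64 µm, 16 cells,
8 h) exists purely for smoke-testing the suite machinery and is too small
for reliable outcome statistics. The acceptance script
(`scripts/acceptance.R`) uses the reduced design throughout.

## What the generator does and does not emulate

The simulations capture the mechanisms the model is about: diffusion-limited
growth stratification, emergent spatial structure (mutualism drives mixing,
competition drives segregation), bacteriostatic inhibition, growth-coupled
detoxification, and the resulting community-level antibiotic responses. They
do not emulate 3D geometry, EPS matrix mechanics, cell death or lysis,
bactericidal antibiotics, detachment and flow, de novo resistance evolution,
or asymmetric interaction strengths — conclusions from passing tests
therefore speak to the model world, not directly to any particular organism.

## Known limitations

* Whole-voxel biomass deposition makes the effective biomass field blocky at
  the 2 µm scale; this is standard for this model class and converges with
  the grid.
* The reduced scale trades statistical power for speed: replicate means of 2
  runs still fluctuate, which is why the headline statistics are large-sign
  effects rather than finely resolved magnitudes.
* At very strong detoxification the antibiotic field develops a depletion
  free boundary; the solver handles it by truncation, but residual-based
  diagnostics inside the depleted region are uninformative (see Numerics).
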