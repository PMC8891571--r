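---
title: "tumorcpm: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tumorcpm: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorcpm)
```

# The model

`tumorcpm` simulates the growth of a small solid tumour, its angiogenic
switch and its response to therapy, by coupling three scales:

* **Intracellular.** A Boolean network of 39 nodes — six receptor-level
  inputs (integrin, RTK, E-cadherin, Wnt and the tumour suppressors APC and
  NF1), 29 internal effectors of the Ras–ERK, PI3K–Akt and Wnt/β-catenin
  cascades, and four outputs — decides each cell's phenotype as a 4-bit
  code over (growth, proliferation, apoptosis, migration). With the inputs
  frozen, the internal network is an acyclic cascade, so every synchronous
  trajectory reaches a fixed point within a dozen updates; sampling or
  exhausting the internal starting states always yields the same four
  attractors (1100, 1101, 0010, 0011), which is the robustness property the
  package verifies rather than assumes.
* **Cellular.** A 3D cellular Potts model (CPM): each biological cell is a
  face-connected set of 4-µm voxels on the lattice, and the dynamics are
  random voxel-copy attempts accepted by the Metropolis rule on the
  effective energy
  \[ H = \sum_{\langle i j\rangle} J_{\tau\tau'}\,(1-\delta_{\sigma\sigma'})
     + \sum_\sigma \gamma_e (v_\sigma - V^T_\sigma)^2
     + \sum_\sigma \alpha\,[\text{cell fragmented}]
     + \chi_\sigma\,\Delta C .\]
  One Monte Carlo step (MCS) makes as many attempts as there are lattice
  sites and represents one minute of real time, anchored to a fastest cell
  cycle of about 24 h.
* **Extracellular.** Reaction–diffusion fields for nutrient, VEGF and a
  cytotoxic drug, with cell-type-dependent capped uptake, sources at vessel
  (endothelial) voxels, secretion by hypoxic tumour voxels and first-order
  decay.

Each minute the simulator derives every cell's receptor bits from its
geometry and the fields, reads the phenotype off the network's input–output
map, performs one CPM sweep, applies growth/division and the viability
state machine, and advances the fields.

# Receptor coupling

The receptor bits are thresholded observables of the cell's
microenvironment: E-cadherin is engaged when the fraction of boundary faces
touching other viable tumour cells reaches `T_cad` (0.3); Wnt turns on when
that fraction drops below `T_wnt` (0.15), reflecting de-repression of
canonical Wnt signalling upon cadherin loss; RTK is gated by the mean
nutrient per voxel against `T_RTK` (4.48e-3 pg/voxel), with a higher
re-entry threshold `T_RTK_Q` (8.96e-3) for quiescent cells so the
quiescence transition has hysteresis; APC and NF1 are scenario flags.

Two couplings deserve comment because the naive reading would make every
tumour impossible:

* **Nutrient-driven RTK silence maps to quiescence, not death.** The
  network sends any RTK-off input to the apoptosis attractor, but
  biologically a starved cell first becomes quiescent; the quiescent state
  is explicitly outside the signalling network's codes. The coupling layer
  therefore distinguishes the cause of RTK silence: starvation routes the
  cell into the quiescent branch of the viability machine (and, after
  `tau_N` = 2 days, necrosis), while pharmacological blockade routes it
  into the apoptosis attractor.
* **Integrin engagement is pervasive in tissue.** The contact-fraction
  reading of integrin (exposed in `receptor_inputs()`) is zero for any
  interior cell of a compact spheroid, which would kill every tumour core
  through the apoptosis attractor. In tissue, however, matrix pervades the
  intercellular space and adherent cells keep integrin engagement. The
  simulation therefore treats integrin as on unless explicitly blocked
  (targeted therapy) or knocked out by a scenario flag.

Apoptosis itself has a commitment delay (`tau_apop`, 12 h): a cell whose
phenotype reverts to a viable code before commitment — for example when a
receptor blockade is lifted — resumes cycling, which is what makes
transient targeted therapy reversible; past commitment the target volume is
set to zero and the cell shrinks out of the lattice.

# Growth, division and the slow first phase

Cells with a proliferative phenotype raise their target volume by one voxel
every `G_grow` = 22 MCS (a volume doubling in roughly one day), pausing
when the actual volume lags more than `lag_max` = 8 voxels behind (space
competition). At twice the initial 64-voxel volume the cell divides along a
random plane; the split is taken at the *median* of the voxel projections
on the plane normal rather than exactly through the centroid, because the
median guarantees balanced daughters (|Δv| ≤ 2) on irregular shapes. The
daughter inherits type and target volume under a fresh id.

Avascular spheroids in culture grow in three phases: a slow aggregation
phase, rapid exponential growth, and a diffusion-limited plateau. The
middle and late phases emerge from the model's energetics and nutrient
budget; the early phase is modelled as junction maturation: a freshly
seeded cell becomes proliferation-competent only after its cadherin contact
fraction has stayed above `T_cad` for `tau_adh` (2 days), encoding the
observation that proliferation requires established adhesive junctions.
Daughters inherit competence, so the lag applies once.

# Transport model and its reduction

The physical transport constants (D_n = 1e3, D_V = 10, D_c = 1.5e3 µm²/s,
VEGF decay 0.9375 h⁻¹) make the nutrient and drug fields four orders of
magnitude faster than the minute-scale lattice dynamics: explicitly
integrating 60 s of real diffusion per MCS would need >2×10⁴ stable FTCS
sub-steps per field per MCS. The production loop therefore splits the
operator: reaction terms (uptake, secretion, sources, decay) are applied
*exactly* over the 60-s MCS — uptake caps are per-voxel (the per-cell cap
divided by the nominal 64-voxel cell volume), decay uses the exact
exponential factor, and removal is always limited by the available
concentration so fields stay non-negative — while diffusion is applied as
`nsub` stable explicit sub-steps per MCS (default 2 per field). The
effective per-MCS diffusion operator that results is the model's transport
calibration; with the defaults it gives an oxygen/glucose penetration depth
of a few cell diameters, which is what produces a hypoxic, VEGF-secreting
core at the observed ~150 µm arrest scale. The op-level integrators
(`step_nutrient()`, `step_vegf()`, `step_drug()`,
`relax_to_quasi_steady()`) honour the physical constants and the stability
bound D·dt/dx² ≤ 1/6 exactly; all analytic-limit checks (exponential
decay, discrete mass conservation, Gaussian kernel, the linear two-plate
steady profile) run through them.

Boundary conditions: domain faces are no-flux; endothelial voxels act as
capped sources for nutrient (release `s_n`, concentration clamped at the
vessel value `n0` = 4.6 pg/voxel), reconciling the source form of the
transport equation with the vessel-surface condition; VEGF starts at zero
and is secreted (0.035 pg/voxel per MCS) by nutrient-starved quiescent and
necrotic voxels; drug is released at vessel voxels only while an infusion
window is active.

The chemotaxis term couples the fields to the CPM through
χ·(C(target) − C(source)) for the extending cell — migrating tumour cells
read the nutrient field, activated endothelial cells the VEGF field. The
printed sensitivities (−1.5×10⁶, −1.61×10⁶) are calibrated to a
concentration unit ~10⁻⁶ of a pg/voxel, so the simulation converts fields
by `kappa_conc` = 1e-6 before applying χ; with pg/voxel fields directly the
chemotactic term would dwarf every other energy.

# Vessels, angiogenesis and immobile states

The pre-existing plexus is generated parametrically: straight vessels of
2×2-voxel cross-section along two planes near opposite domain faces,
segmented into 64-voxel endothelial cells (the published geometry is only
described as regular and ordered, so the generator's spacing is a
documented, non-canonical default). Quiescent vessel ECs are immobile in
the CPM (mature vessels are stable); an EC whose mean VEGF reaches
`T_v` = 9.5e-4 pg/voxel activates, responds chemotactically to the VEGF
gradient and proliferates while its EC–EC junction fraction stays below
`theta_VE` = 0.65 (VE-cadherin contact inhibition; a threshold of 1
disables inhibition). Necrotic cells are likewise frozen and are cleared
`tau_clear` = 5 days after necrosis. Quiescent tumour cells are frozen by
default as well (`freeze_quiescent`): their membrane activity is
negligible, and this makes the post-arrest plateau computationally cheap.

# Therapy

Chemotherapy maps the body-surface-area dose linearly onto the printed
release interval (5 µg/m² ↦ 2.55e-16, 10 µg/m² ↦ 5.1e-16 mol/cell/s) and
releases drug from every vessel voxel for the first day of each cycle.
Only proliferating/migrating cells take up drug; cumulative uptake beyond
θ₁ arrests the cell (mitotic arrest — such cells keep taking up drug,
which is what lets the lethal threshold be reached at all), beyond θ₂ it
dies by necrosis and is counted as a therapy kill. Damage is repaired with
a one-day half-life, so sub-lethal exposure is transient and low-dose arms
genuinely relapse. Under protocol concentrations the uptake operates in
the linear branch of the uptake function (the cap `rho_mult`·κ_P rarely
binds), making cumulative uptake dose-proportional — without this the cap
saturates and every dose kills identically. θ₁ = 1600 and θ₂ = 4000 pg
were calibrated once on the compact vascular fixture so that the
10 µg/m² five-cycle arm eradicates while 5 µg/m² fails, and then frozen.

Targeted therapy is receptor blockade, no pharmacokinetics: the listed
receptors are forced off in every tumour cell's input during the block
window. Blocking RTK (or integrin) sends every tumour cell into the
apoptosis attractor within one re-evaluation; lifting the block before
commitment rescues the cells and growth resumes.

Treatment efficacy is summarised by the fraction of killed cells,
FKC(t) = kills(t) / (viable cells at therapy start + births since),
clamped to [0, 1], and by a four-way outcome classification (eradicated,
dormant, relapse, failure) over the volume trace.

# Numerical and design choices

* **Update scheme.** Synchronous Boolean updates (deterministic); an
  asynchronous random-order mode exists for robustness exploration only.
  Cycle attractors (absent from the shipped cascade but possible for user
  networks) read out with a strict AND across cycle states.
* **Continuity term.** The printed Kronecker form of the continuity energy
  is degenerate as written; it is implemented as a penalty of α = 300 per
  cell whose voxel set is not one face-connected component. The
  incremental ΔH evaluates this exactly: a simple-point local connectivity
  check around the lost voxel proves most moves safe, and the rare
  inconclusive cases fall back to a component count over the cell, so the
  incremental energy equals the brute-force Hamiltonian difference to
  floating precision (this equality is an acceptance test).
* **Metropolis bookkeeping.** One uniform draw decides site and direction;
  for unfragmented cells the continuity term is non-negative, so a
  rejection based on the cheap partial ΔH bound is exact and skips the
  connectivity work.
* **Units.** Internal concentrations are pg/voxel. Mol-based table rates
  convert once through declared constants (nutrient 1.8e14 pg/mol,
  glucose-scale; drug 8.54e14 pg/mol, taxane-scale) divided by the
  64-voxel cell volume; both constants are explicit config entries.
* **Adhesion matrix.** The symmetric reading of the published coefficient
  table, with J(medium, medium) = 6 (the alternative trailing-digit
  reading 66 is config-accessible); first-order (6-neighbour) contact sums
  by default, second order available.
* **RNG.** All randomness (scenario synthesis, sweeps, division planes)
  flows through R's seeded generator; a run is bitwise reproducible for a
  fixed seed and configuration, and every writer records the seed and a
  hash of the configuration.

# Scaled study conditions

The full-scale setting (150×150×200 lattice, 65-µm tumour, multi-month
runs) exceeds a desk machine, so the packaged studies run on scaled
fixtures chosen once:

* `spheroid50` — 50³ closed avascular domain, 65-µm tumour, 12 simulated
  days. It reproduces the three-phase growth curve (slopes ≈ 0.35, 0.65,
  −0.03 log-volume/day in the shipped example) and arrests at ≈160 µm
  diameter with a hypoxic VEGF-secreting core forming before arrest.
  Because the closed domain has no nutrient source, the post-arrest tumour
  eventually necroses completely — a fixture property, not a claim about
  perfused tissue.
* `vascular32` — 32³ domain, 32-µm tumour between two vessel planes,
  junction-maturation lag disabled; used for the therapy ordering studies
  (5 seeds per arm, doses 5/7.5/10 µg/m², two-day cycles).

What passing these scaled studies shows is that the mechanisms — contact
regulation, nutrient-limited arrest, dose-dependent kill, blockade-driven
apoptosis — behave and order correctly; it does not reproduce full-scale
absolute numbers (arrest day 33, EC counts), nor features of real tumours
the model omits: blood flow and vessel remodelling, interstitial pressure,
immune response, drug resistance evolution, and sub-voxel mechanics.

# Known limitations

The reported sensitivity claim that a low cadherin threshold (< 0.2)
completely inhibits proliferation is not reproducible from the phenotype
map itself (cadherin-on inputs yield a proliferative code, and lowering
the threshold only turns cadherin on more often); the package tests the
monotone RTK-threshold sensitivities instead. The Boolean cascade's lack
of feedback loops makes attractor analysis trivial by construction —
convenient for robustness, but it means oscillatory signalling phenomena
are out of reach. Vessel geometry, EC chemotaxis strength and the drug
damage thresholds are calibrated model constants, not measured quantities.
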