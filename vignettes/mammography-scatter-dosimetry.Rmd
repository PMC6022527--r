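---
title: "Methods: Monte Carlo scatter dosimetry for the thyroid in mammography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo scatter dosimetry for the thyroid in mammography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mammoscatter)
```

# The problem

At mammographic tube voltages (26–35 kV) the photoelectric effect dominates
photon interactions in tissue, so absorption is strong and the scatter that
does escape is dominated by large-angle (Thomson-like) events. The thyroid,
a few centimetres above the compressed breast, therefore receives a small
but non-zero scattered dose, and the question of whether a lead-equivalent
thyroid collar is worthwhile is quantitative: how large is the surface air
kerma at the thyroid position, how much of it comes from the breast side
versus the tube/collimator side, how small is the thyroid organ dose after
tissue attenuation, and how does all of this compare with the mean
glandular dose (MGD) that the examination exists to deliver?

`mammoscatter` answers these questions with a transparent, fully seeded
Monte Carlo model plus the analytic and statistical machinery around it.

# Model components and assumptions

## Tube spectrum

The unfiltered bremsstrahlung fluence follows the Kramers form
$N(E) \propto (kVp - E)/E$, integrated over 0.25 keV bins from 8 keV (the
tube window removes the band below 8 keV) to the set voltage. Two
filtration stages shape it:

* *anode self-filtration*: an effective tungsten path, default 3 µm.
  The default was calibrated so that the 28 kVp W/Rh half-value layer is
  ≈ 0.51 mm Al, the published beam quality of this anode/filter class;
  without it the bare Kramers form is distinctly too soft (HVL ≈ 0.44 mm).
  The heel effect's angular variation is not modelled; the focal spot is a
  point.
* *added filtration*: 50 µm rhodium by default; the Rh K edge at 23.22 keV
  produces the characteristic W/Rh spectral cut.

Tungsten L lines (8.4/9.7 keV) can be added but are off by default — the
rhodium filter suppresses them to irrelevance. `half_value_layer()` is the
QA handle; `mas` enters only as a linear photon-count normalisation.
Whether the reference exposures should be read as full spectra at 28/35 kVp
or mono-energetic 28/35 keV beams is ambiguous in the source description;
both modes exist (`generate_spectrum()` vs `mono_spectrum()`) and the
spectrum mode is the default for all shipped scenarios.

## Phantom

The scene is a constructive stylized phantom voxelised at 2 mm (isotropic,
half-open voxel boxes, right-handed mm coordinates: z vertical, beam −z in
the CC view, y anterior, chest-wall plane y = 0, breast-support top z = 0):

* elliptic-cylinder torso (half-axes 170 × 110 mm), neck cylinder (r 50 mm)
  recessed 10 mm behind the chest-wall plane, ellipsoidal head with brain;
* two-lobe thyroid (9 × 9 × 21 mm semi-axes per lobe, plus isthmus) at
  anterior neck height z ≈ 200 mm, lobe front ≈ 7 mm below the skin; mass
  ≈ 17 g. A reference cross-section area of 4 cm² is carried in the scene
  manifest for fluence bookkeeping only — it cannot be reconciled with a
  ~20 g gland simultaneously, and mass (the dosimetric quantity) wins;
* box/cylinder organs for the ICRP 103 bookkeeping: lungs, liver, stomach,
  bladder, intestine (colon), gonads, oesophagus, salivary glands, spine
  (cortical shell + red-marrow core), skin (the outermost voxel layer of
  the body by 6-neighbour erosion), a contralateral breast ellipsoid and a
  single remainder-proxy organ carrying the full ICRP remainder weight;
* the imaging chain: compressed breast slab (17 × 14 cm footprint,
  3–7 cm thickness, 3:2 fat/glandular mixture at 0.98 g/cm³, or PMMA for
  phantom-study configurations), 2 mm PMMA paddle, PMMA support plate and
  an aluminium-equivalent detector slab. It displaces air only — it never
  carves into the body;
* the x-ray head, reduced to its lead bottom wall (1 mm) with the beam
  aperture as a hole; the source is collimated into the aperture cone with
  an 8% linear margin so the aperture edge is genuinely irradiated, which
  together with a 2 mm PMMA face shield 50 mm below the focus constitutes
  the collimator-side scatter source. Side and top walls are unreachable by
  construction (the "no leakage" configuration);
* two 2 × 2 × 1-voxel air probes at the anterior neck midline at thyroid
  height — `probe_inner` just outside the skin and `probe_outer` 4 mm
  further out — with the optional 0.25 mm lead collar sheet between them.
  A geometry check refuses any collar that intersects the primary beam
  pyramid.

The MLO view rotates the imaging chain (slab, paddle, support, detector,
focal spot, aperture wall) by 45° about the anterior axis through the
slab's medial edge; the anatomy does not deform. Organ masses agree with
the constructive-solid volumes to discretisation accuracy, and scene
construction is deterministic (the manifest records a config hash).

Free parameters the source material does not print — thyroid depth, neck
recess, probe stand-off, source-to-image distance (650 mm default) — are
single a-priori anatomical choices recorded in the manifest; the scenario
bundle reports the resulting dosimetry rather than assuming it.

## Transport and estimators

Transport is analog (all statistical weights are 1):

* **Free flight** inside the voxel grids uses Woodcock delta-tracking
  against an energy-dependent global majorant (the maximum linear
  attenuation over the scene's materials at the photon's energy). Outside
  the grids (the tube-to-paddle air column) flights are sampled from the
  exact piecewise optical depth instead of delta-stepped, purely for speed.
* **Interactions**: photoelectric absorption (local deposition — the kerma
  approximation, justified because secondary-electron ranges are below
  0.03 mm at these energies, far below the 2 mm voxels); incoherent
  scattering with free-electron Klein–Nishina angle/energy sampling;
  coherent scattering with the Thomson angular shape (no form factor; at
  high Z this overstates large-angle coherent scatter somewhat, an
  acknowledged approximation).
* **Lead** is excluded from the majorant (its attenuation coefficient would
  cripple delta-tracking everywhere) and represented as thin analytic
  boxes: interaction points inside lead are sampled from the exact
  Beer–Lambert law along each flight segment, with analog PE / incoherent /
  coherent channels and a single-line L-fluorescence approximation
  (10.55 keV, effective yield 0.29, emitted above the L3 edge, default on).
* **Organ doses** use the delta-collision kerma estimator: every tentative
  collision (virtual or real) at energy E in a voxel of material m adds
  $E\,\mu_{en,m}(E)/\mu_{maj}(E)$ to the voxel's organ, an unbiased
  track-length-equivalent estimator. MGD uses the same estimator with the
  glandular mass-energy-absorption coefficient over the breast-slab volume.
* **Probe kerma** uses a next-event (point-detector) estimator: every real
  collision contributes its expected scatter toward each probe point,
  channel-probability-weighted, with the Klein–Nishina or Thomson angular
  pdf, the ray-traced optical depth to the probe, and the scattered (not
  incident) energy in the air-kerma weighting. The $1/r^2$ kernel is
  softened to $1/(r^2 + 4\,\mathrm{mm}^2)$, which approximates averaging
  over the probe volume and bounds the estimator variance for collisions in
  the adjacent skin. The uncollided (primary) component is added
  analytically. Provenance classes — primary, breast-side backscatter
  (breast, body, support, detector, ambient air), collimator-side scatter
  (paddle, face shield, head wall), collar-transmitted — are assigned by
  the region of the photon's last real interaction, with collar crossings
  taking precedence.
* **Uncertainties** come from history batching (20 batches by default);
  the per-batch energy ledger (emitted = deposited + escaped + cutoff)
  balances exactly because transport is analog, and the suite checks it to
  1e-6.

Per-history tallies are normalised to clinical exposures by equating the
analytic free-in-air entrance kerma at the paddle-entrance reference point
(beam axis, upstream attenuation included, no backscatter, no paddle
transmission — the incident-air-kerma convention) with the protocol's
entrance dose per view, 3.6 mGy by default. Right-breast exposures reuse
left-breast tallies by mirror symmetry, which the output flags.

## Dosimetry

Effective dose applies the embedded ICRP 103 weights directly to the female
phantom's organ doses (no sex-averaging — deliberately, to reproduce the
source bookkeeping). The breast equivalent dose is the mean glandular dose
over both breasts. Two deliberate conventions:

* the 13 ICRP remainder tissues are one remainder-proxy organ carrying
  w = 0.12 (the arithmetic-mean rule collapses onto the proxy mean dose);
* the skin equivalent dose rescales the phantom skin dose by
  (phantom skin mass)/(2300 g reference female whole-body skin), because
  the limbless phantom would otherwise overstate the mass-averaged skin
  dose by concentrating the directly irradiated slab surface in a partial
  shell.

`scaled_effective_dose_increase()` implements the collar-relevance check —
multiply every organ dose except the directly irradiated breast by a
measurement/simulation conversion factor and recompute E — and its closed
form $100\,(f-1)(1-f_{breast})$ is verified against the direct computation
in the tests.

## Shielding

`transmission()` and `spectrum_transmission()` are narrow-beam
Beer–Lambert, with fluence or air-kerma weighting for spectra; no buildup
factors (broad-beam collar physics is what the Monte Carlo runs are for).
The spectrum-weighted value is only asserted to be bounded by the
mono-energetic transmissions at populated bins — it has no simple
relation to the minimum-attenuation energy alone.

## Synthetic cohort

`generate_cohort()` emulates the 82-patient collar study: group sizes
27/22/33 (L/M/S), group-conditional truncated-normal compressions matching
the published means and SDs, an automatic-exposure rule mapping compression
to tube voltage (clipped to 26–32 kV) and mAs (36–237), the exponential
outside-dose law $K = 52.87\,\mu Gy\,e^{0.2194\,cm^{-1} C}$ on the CC
compression (interpreted as the CC+MLO two-view sum) with lognormal
multiplicative noise of CV 0.5 — calibrated so the cohort standard error of
the outside dose reproduces the published 0.187 ± 0.011 mGy at n = 82 — a
BMI marginal N(25, 4) truncated to [17, 45] coupled to the outside dose
through a Gaussian copula at target correlation 0.48, and an inside dose
dominated by an effective scatter-leakage transmission of 0.08 (the
published behind-collar readings are 6–10% of the outside dose, far above
the ~0.1% direct lead transmission, so Beer–Lambert alone would be wrong)
plus a small additive floor. Fixed seeds give bit-identical cohorts.

What the generator does **not** emulate: real anatomical correlation
structure beyond the printed moments, paddle-size effects on dose,
measurement-device response. Passing statistics tests on this cohort
demonstrates the pipeline's correctness on data with the study's moments,
not agreement with the real population.

## Statistics

Paired t, one-way ANOVA with Tukey HSD (the Tukey–Kramer form handles the
unequal group sizes), and Pearson correlation wrap the standard R
implementations; the tests verify them against hand formulas and the
studentized-range distribution. The exponential fit is unweighted nonlinear
least squares on the natural scale (a log-scale option exists), initialised
from the log-linear regression, converged to 1e-10; parameter-recovery
simulations (200 replicate cohorts) check median bias < 5% and ±2 SE
coverage within [90%, 99.5%]. All tests are two-sided with α = 0.05.

# Numerical choices

* Coefficient interpolation is log-log linear with grid points bracketing
  the Rh K and Pb/W L edges; the transport kernel pre-tabulates linear
  coefficients on a 0.05 keV grid (5–40 keV) with power-law extrapolation
  below the 8 keV table edge (nothing physical reaches it).
* Energy cutoff 5 keV (deposit locally); spectrum support starts at 8 keV.
* Mixture density follows the harmonic mass-weighted rule unless
  overridden (the breast mixture is pinned at 0.98 g/cm³).
* Degenerate statistics inputs (identical paired vectors, zero-variance
  correlations) raise errors or return the documented t = 0 / p = 1 case.
* Ties in the delta-tracking boundary arithmetic are broken by a 1e-6 mm
  nudge across interfaces.

# Problem sizes

The shipped test suite runs transports of 2.5 × 10⁴ – 2 × 10⁵ histories
(about a minute in total); the acceptance script uses 2 × 10⁶ histories per
view for the protocol simulation and 10⁶ per backscatter run, a couple of
minutes on one core. Batch standard errors on the headline kerma quantities
are ~1% at the protocol sizes.

# Known limitations

* The stylized anatomy is not a reference computational phantom: thyroid
  depth, neck pose and chin shadowing differ from segmented-human models,
  and the surface kerma and thyroid dose at the neck are sensitive to
  them. The scenario bundles report these quantities with uncertainties
  rather than presenting them as anatomy-independent.
* The provenance taxonomy assigns compression-paddle scatter to the
  collimator class (it is machine-side); diagnostic runs show that class is
  dominated by the paddle, so backscatter/collimator shares under other
  taxonomies differ materially.
* Coherent scattering lacks form factors and incoherent scattering lacks
  the incoherent scattering function inside the transport kernel (they are
  present in the embedded integrated cross-sections); angular distributions
  at high Z are approximate.
* No electron transport (kerma approximation), no polarisation, no
  off-focal radiation, no tube-output calibration in µGy/mAs.
* The embedded coefficient tables are first-principles (Cromer–Liberman
  photoabsorption, IT92 form factors) and agree with published tabulations
  to ~3% in this band; dose ratios cancel most of that.
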