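---
title: "Static catalytic fields: model, probes and the substituent regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static catalytic fields: model, probes and the substituent regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catfield)
```

## The model

The activation barrier of a reaction embedded in a molecular environment
changes, to electrostatic leading order, by

$$\Delta \;\approx\; \sum_i q_i^{C}\,\bigl(V^{TS}(\mathbf r_i) - V^{S}(\mathbf r_i)\bigr),$$

the difference of the environment's Coulomb interaction with the transition
state and with the substrate, summed over the point charges $q_i^C$
representing the environment. This is the electrostatic term of
differential transition-state stabilization; everything else (exchange,
induction, charge transfer, mesomeric redistribution) is outside the model.
Because the sum is exactly additive, the response to *any* environment is
characterized by one scalar field, the static catalytic field

$$\Delta_s(\mathbf r) = -\bigl(V^{TS}(\mathbf r) - V^{S}(\mathbf r)\bigr),$$

the barrier lowering a unit **positive** probe charge at $\mathbf r$ would
produce. The package stores $\Delta_s$ with exactly this sign everywhere;
any sign-flipped presentation (e.g. plotting $-\Delta_s$ against observed
barrier changes) is left to the caller, never baked into a data structure.

Three assumptions matter in practice:

* **Rigid, superimposed states.** $V^{TS}$ and $V^{S}$ must be evaluated in
  one common frame. The transition state is always the mobile structure,
  aligned by `kabsch_superpose()` over a user-chosen conserved subset
  (alignment over *all* atoms is usually wrong: S and TS differ most near
  the reacting bond, so align on the spectator skeleton).
* **Vacuum, unpolarized electrostatics.** No dielectric screening, no
  penetration or polarization corrections, no periodicity.
* **Point-potential response.** A substituent is represented by the field
  value at a single probe point; this breaks down in the direct vicinity of
  the reacting region, which is why near-reaction sites are flagged and
  excluded from the regression by default.

## Potentials from atomic multipoles

$V$ is generated from atom-centred (cumulative) multipole moments read from
a CSV table: monopoles `q` (e), optional dipoles `mux,muy,muz` (e·bohr) and
quadrupoles `qxx..qzz` (e·bohr²). Evaluation is in atomic units with the
conversions pinned in `field_constants()` (627.509474 kcal mol⁻¹/hartree,
0.5291772109 Å/bohr), so a unit charge at 1 Å gives 332.0637 kcal mol⁻¹ e⁻¹
exactly:

```{r}
m <- molecule("H", matrix(0, 1, 3))
potential_at_point(m, multipole_set(q = 1), c(1, 0, 0))
```

**Quadrupole convention.** Tables are detraced on load (trace/3 subtracted
from the diagonal, with a warning above |trace| = 1e-8) and the quadrupole
term is evaluated as $\sum_{ij}\Theta_{ij}(3R_iR_j - R^2\delta_{ij})/(2R^5)$.
These two choices are one convention: $\Theta$ is the *detraced second
moment* $\sum q(\mathbf r\mathbf r^\top - r^2 I/3)$, under which the
detraced table of any raw second-moment output gives the exact potential.
QM programs emitting the Buckingham-normalized tensor (an extra factor 3/2)
must be rescaled before import; the reader is deliberately agnostic about
which population analysis produced the charges.

**Truncation order** defaults to 2 (quadrupole). The expansion converges
rapidly beyond roughly 2 Å from the nearest atom; probes placed 1.5 Å
outside the van der Waals envelope are comfortably in that regime. The
order-by-order difference at bond probes is a useful convergence
diagnostic, but it is geometry-dependent and therefore reported, not
asserted. A hard guard refuses evaluation within 0.3 bohr of any centre,
where the series diverges: failing loudly beats returning a huge number.

## Probe placement

* **Bond-directed probes** (`place_bond_probes()`): at distance $d$ (default
  1.5 Å) beyond the site hydrogen along the heavy-atom→H bond vector. The
  literature states only the distance; the bond direction is this package's
  choice of where a substituent's charge centre sits — the natural one for
  an atom replacing H, but an assumption nonetheless, so the distance is a
  parameter and the construction is a separate, testable function.
  Each site H must have exactly one heavy neighbour within 1.3 Å.
* **Surface probes** (`place_surface_probes()`): a deterministic Fibonacci
  lattice on each atom's sphere of radius $r_{vdW} + r_{probe}$ (Bondi
  radii; water probe 1.4 Å by default), keeping points outside every other
  atom's enlarged sphere — the solvent-accessible surface. Density defaults
  to 1 point/Å², enough for a qualitative map; raise it for rendering.
  Probes are defined on the substrate-state geometry after TS superposition,
  so one probe set serves both potentials.

## The substituent regression

`fit_field_model()` regresses observed barrier changes on $\Delta_s$ at the
site probes by ordinary least squares, reporting the slope, intercept and
residual SD $\sqrt{SSR/(n-p)}$. Decisions taken where the design was open:

* **Intercept included by default.** It absorbs systematic
  non-electrostatic offsets common to all sites; the no-intercept variant
  is one flag away and is compared in testing against a closed-form
  normal-equations oracle.
* **"Standard deviation"** is interpreted as the residual SD about the
  fitted line, with $p$ equal to the number of fitted coefficients.
* **Near-reaction sites** (H within 3.0 Å of a reacting atom by default)
  are excluded from fitting but still predicted: at those positions the
  point-potential picture is overly simplistic even when electrostatics
  dominates.
* **Ranking signs are derived, not hardcoded.** From the single-charge
  identity $\Delta = -q\,\Delta_s$, a substituent carrying effective charge
  $q$ lowers the barrier most where $-q\,\Delta_s$ is most negative; for the
  default electronegative substituent ($q = -1$ e) that is the most
  *negative* $\Delta_s$. `rank_sites()` exposes the charge sign as a
  parameter, breaks ties by ascending site index, and reverses exactly under
  the opposite objective.

```{r}
d <- make_linear_dataset(n_sites = 50, slope = 0.15, intercept = 0.5,
                         noise_sd = 1.0, seed = 1)
fit_field_model(d)
```

## What the synthetic fixtures do and do not establish

The package carries no quantum-chemical data, so its test systems are
generated:

* `make_proton_shift_pair()` — a +1 e proton moving between two −0.5 e
  anchors (defaults: 2.5 Å separation, a typical strong-H-bond
  donor–acceptor distance; 0.5 Å shift, about half a transfer path). The
  S and TS proton positions are placed symmetrically about the anchor
  midpoint, so $\Delta_s$ vanishes on the perpendicular bisector by mirror
  symmetry for every shift — an exact, analytically checkable feature. All
  charges are monopoles, so every potential is hand-summable.
* `make_random_multipole_cloud()` — neutral clouds (charges N(0, 0.3 e),
  1.2 Å minimum separation in a 6 Å box, small random dipoles/quadrupoles)
  exercising the order-1/2 code paths against explicit finite-charge
  cluster oracles.
* `make_linear_dataset()` — the regression's stated world: $\Delta_s \sim
  U(-10, 10)$ kcal mol⁻¹ e⁻¹, true slope 0.15 e, intercept 0.5, Gaussian
  noise SD 1.0 kcal mol⁻¹, 50 sites — magnitudes typical of an H→F
  substitution series.

A green suite establishes that the electrostatics, geometry and regression
machinery are exact to their stated tolerances on systems whose answers are
independently computable. It does **not** establish agreement with any
quantum-chemical barrier: real substituent effects include mesomeric and
exchange contributions the model excludes by construction, and real
multipole tables inherit the charge-model ambiguity of their provenance.

## Numerical choices

* Conversion constants pinned once (`field_constants()`); all modules agree
  bit-for-bit.
* Kabsch reflection branch corrected by flipping the smallest singular
  vector; collinear or <3-point pairings are refused rather than silently
  resolved.
* Proximity guard 0.3 bohr; PDB B-factors clamped at ±999.99 (fixed-width
  column) with a warning; XYZ written at 8 decimals; multipole CSV at full
  double precision.
* All fixture randomness flows through `withr::with_seed`: same seed, same
  fixture, bitwise, and the caller's RNG state is never touched.

## Known limitations

Single-determinant point-potential model: no mesomeric, polarization or
penetration terms; no multi-TS networks; no automatic atom correspondence
for the superposition subset; reverse reactions need their own substrate
endpoint (sign-flipping the forward field is only valid when both wells
share one TS geometry, so the package never does it implicitly).
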