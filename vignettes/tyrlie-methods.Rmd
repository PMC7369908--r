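---
title: "Methods: LIE binding affinities and the Cu2+ dummy-site model"
author: "tyrlie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LIE binding affinities and the Cu2+ dummy-site model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyrlie)
```

This vignette is the package's account of its science: the estimator and
its assumptions, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical and design choices
made where the method leaves room.

## The linear interaction energy estimator

Rigorous alchemical routes to a binding free energy (free energy
perturbation, thermodynamic integration) sample many nonphysical
intermediate states and are expensive. LIE is an *end-point*
approximation: only the two physical ensembles are sampled — the ligand
bound in the solvated protein, and the ligand free in solvent — and the
binding free energy is taken linear in the change of the ligand's average
interaction energies with its surroundings,

$$\Delta G_{\mathrm{LIE}} =
\alpha\,(\langle V_{vdw}\rangle_{bound} - \langle V_{vdw}\rangle_{free})
+ \beta\,(\langle V_{ele}\rangle_{bound} - \langle V_{ele}\rangle_{free}).$$

The electrostatic half of this form follows from linear-response theory
(hence $\beta$ near $\tfrac12$ for rigid polar environments); the van der
Waals half is empirical, absorbing size-dependent effects such as the
hydrophobic contribution. Assumptions worth keeping in mind: both
ensembles are equilibrated and stationary over the analysis window; the
response of the environment is approximately linear in the ligand's
charges; and conformational strain and explicit entropy terms are folded
into the scaling factors rather than modeled.

Two parameterizations are implemented:

* **Model 1 (literature).** $\alpha = 0.181$ fixed
  (`LIE_ALPHA_LITERATURE`), $\beta$ set by ligand chemistry through
  `assign_beta()`: charged ligands 0.50; neutral ligands with zero, one,
  or two-plus hydroxyl groups 0.43, 0.37, 0.33. A per-ligand override
  column in the shipped descriptor table takes precedence. The overrides
  were back-derived from the reference per-ligand estimates
  ($\beta = (\Delta G - \alpha\,\Delta V_{vdw})/\Delta V_{ele}$, which
  lands on the published class values to input rounding); they encode,
  rather than guess, the reference parameterization for the two ligands
  (l-Tyr, KA4) whose hydroxyl/backbone chemistry does not resolve cleanly
  under the naive counting rule (l-Tyr carries a zwitterionic backbone,
  KA4 a carboxylic acid).
* **Model 2 (fitted).** Both factors estimated by least squares against
  experimental affinities, see Calibration.

Uncertainties propagate in quadrature throughout
(`compute_delta()`, `lie_binding_energy()`), treating bound and free
samples, and the two components, as independent.

## Energy time series and block averaging

MD interaction energies written every few dozen integrator steps are
strongly autocorrelated, so the naive $s/\sqrt{n}$ standard error is
optimistic. `block_average()` uses the standard remedy: split the series
into $k$ contiguous blocks and report the standard deviation of the block
means over $\sqrt{k}$. The default is $k = 5$; it is a convention, not an
estimate of the true correlation time, and is configurable. With $k = 1$
no spread is measurable; the summary then carries `sem = 0` plus a
`degenerate` flag and a warning, rather than an invented number. The
reference uncertainty column shipped with the package is carried as data
for display — its original estimator (blocks, replicas, or raw SD) is not
recorded in the source material, so the package does not claim to
reproduce it.

Windowing (`window_series()`, or `t_start`/`t_end` on `block_average()`)
is the caller's responsibility; production practice is to analyze a late,
equilibrated window (e.g. the last 4 ns of a 10 ns run). The defaults use
all frames because the synthetic series are stationary from frame one.

## Experimental affinities

`delta_g_from_ki()` converts an inhibition or dissociation constant to a
free energy by $\Delta G = RT \ln K$ with
$R = 1.987204\times10^{-3}$ kcal/(mol K) and $K$ in molar. The default
temperature is 298.15 K: the reference experimental free-energy column is
reproduced with a maximum deviation of 0.05 kcal/mol at 298.15 K and
slightly worse at 300 K, so the package adopts 298.15 K and leaves the
temperature configurable. Dissociation constants (the l-Tyr substrate) are
converted identically — the distinction matters thermodynamically but the
reference treats them alike. No IC50 conversion or standard-state
correction is attempted.

## Calibration

`fit_lie_parameters()` solves

$$\min_{\alpha,\beta} \sum_i \left(\Delta G^{exp}_i
  - \alpha\,\Delta V_{vdw,i} - \beta\,\Delta V_{ele,i}\right)^2$$

by the 2×2 normal equations, **with no intercept**: the estimator passes
through the origin by construction, and refitting the reference table
without an intercept lands on the published factors almost exactly
(α = 0.197, β = 0.342) while an intercept model does not. Ligands without
measured constants (l-DOPA) are excluded, leaving 8 points. If the normal
matrix condition number exceeds $10^{12}$ the fit fails loudly instead of
regularizing — a silent ridge fit would misrepresent the method.
`coefficient_of_determination()` is the squared Pearson correlation of
predictions against observations (hence sign- and affine-invariant — it
measures association, not absolute agreement), matching how
predicted-vs-observed $r^2$ values are conventionally reported.
`leave_one_out()` is an added robustness check the original workflow
implies but does not perform; on the reference table the refit α stays in
(0.19, 0.21), indicating no single ligand drives the calibration.

One known irreducible discrepancy: applying the fitted (0.197, 0.342) to
the *rounded* reference $\Delta V$ columns deviates from the reference
model-2 column by up to ~0.2 kcal/mol with a systematic sign, consistent
with the original fit having been applied to unrounded energies. The
package documents this rather than tuning toward it; the model-2 $r^2$
(0.94) is unaffected at its printed precision.

## Decomposition

`residue_profile()` time-averages per-residue/per-ion bound-state series;
`top_contributors()` ranks by most-negative mean (strongest attraction),
with lexicographic tie-breaks, because that is how per-residue profiles
are read in practice — a large positive (repulsive) term is not a binding
determinant. `ion_contributions()` pairs each copper ion's electrostatic
mean with its mean ligand–ion distance. These are averages of interaction
energy terms, not free-energy components — there is no rigorous
decomposition of a free energy into per-residue contributions — and every
serialized profile carries that caveat in its header.

## The dummy-atom Cu²⁺ site

Classical force fields struggle with bare divalent metals: a +2 point
charge over-polarizes its shell and binuclear sites repel excessively.
The dummy-site representation spreads the +2e over a central core and six
massless charged dummies in an octahedron, held at fixed class distances
from the core. Because a d⁹ Cu²⁺ octahedron is Jahn–Teller active, the
two axial dummies sit at an elongated distance relative to the four
equatorial ones, and the model's axial direction is physically meaningful.

`build_dummy_model()` enforces, for any parameter values: exact charge
conservation (core + 4·eq + 2·ax = +2.0 e), exact class distances (to
1e−9 Å), axial ≥ equatorial distance, and an orthogonal equatorial
quartet. The orientation rule: the axis points at the coordinating
partner with the largest metal–partner distance — the elongated contact
is the axial one (His208 for Cu_A, His60 for Cu_B in the reference
coordination table) — overridable by name when a site's axial partner is
ambiguous (e.g. whether an axial water co-defines the axis). The
equatorial quartet is then rotated about the axis to minimize the summed
angular deviation to the remaining partners (coarse 0.5° grid over the
π/2-periodic objective, refined by golden-section search; the objective
is piecewise-smooth so the grid guards against the wrong local valley).
Fewer than three coordinating partners, or a coordination shell collinear
with the axis, is an error — the frame is underdetermined.

The shipped numeric charges (0.0/+0.32/+0.36 e) and distances
(0.9/1.1 Å) are **placeholders**: the published force-field values live
in the original dummy-model literature and are deliberately not restated
as authoritative; nothing the package validates depends on them beyond
the invariants above.

Geometry validation on trajectories: `coordination_distances()` (per
partner mean ± SD of the metal–partner distance),
`jahn_teller_score()` (mean axial over mean equatorial distance; > 1 is
axial elongation, exactly 1 for a perfect octahedron), and
`radial_distribution()`. The RDF is normalized by spherical-shell volume
and by the mean density of the selected species *within the analysis
sphere* — the local-density convention appropriate to a non-periodic
spherical droplet, where the usual box-density normalization is
undefined.

## Synthetic data: what it emulates, and what it does not

The generators make the pipeline testable without an MD engine.

* `gen_energy_series()` draws a stationary Gaussian AR(1) process:
  marginal $N(\mu, \sigma^2)$, lag-1 autocorrelation $\varphi$ (default
  0.9, reflecting energies saved every 25 steps of a 2 fs integrator,
  with frame spacing 0.05 ps). AR(1) reproduces the one feature of MD
  energy traces the analysis is sensitive to — autocorrelation inflating
  the variance of time averages — and nothing else.
* `gen_bound_free_pair()` enforces the requested $\Delta V$ exactly in
  the population means. Free-state means are not observable by the
  estimator (only differences enter), so they default to fixed fractions
  of the bound means (free = 0.27·bound electrostatic, 0.5·bound van der
  Waals, placing the kojic-acid bound electrostatic mean near
  −25 kcal/mol, a realistic magnitude for a polar ligand in a charged
  site).
* `gen_site_trajectory()` puts each partner on a fixed octahedral
  direction (axial partners on ±z) with i.i.d. Gaussian radial distances
  at the target mean/SD, so distance statistics are recovered
  asymptotically.
* Simulation sizes: 2000 frames per series/trajectory, noise SD
  0.2–0.5 kcal/mol for energy series. At these sizes the standard error
  of a series mean is ~0.02 kcal/mol, an order of magnitude below the
  0.2–0.5 kcal/mol scale on which the conclusions live.

What passing tests on these inputs shows: the estimators, the
calibration, the decomposition bookkeeping, and the geometric validators
are correct on data with the statistical structure the analysis assumes.
What it does not show: anything about force fields, sampling convergence,
water structure, or whether real trajectories satisfy those assumptions —
the generators have no physics beyond their first and second moments. In
particular, the reference coordination table's ± values are *targets
given to the generator*, not reproduced simulation output.

All generators take integer seeds and are bit-reproducible per seed
(R's Mersenne–Twister behind a state-preserving wrapper).

## Degenerate inputs and numerical conventions

* Energies must be finite; a `NaN` in an input table is a parse error
  with a line number, not a silent drop.
* Duplicate (identity, time) rows are rejected; within-series order is
  by time.
* Summary tables serialize at fixed 6-decimal precision so
  write→read→write is byte-identical.
* PDB output keeps original records verbatim and appends 7 HETATM
  records per site (core `CU`, dummies `DE1`–`DE4`/`DA1`–`DA2`, residue
  `DUM`, element `D`), with fresh serials; re-augmenting an augmented
  file is a naming error. Coordinates round-trip at PDB's 3-decimal
  precision.
* `coefficient_of_determination()` refuses zero-variance vectors and
  fewer than 3 pairs rather than returning `NA`.

## Known limitations

* β assignment for chemically ambiguous ligands is an override table,
  not a rule; applying the package to new ligands outside the shipped
  set means choosing β by their chemistry class or refitting.
* The decomposition is presentation-level by design (no MM/PBSA-style
  per-residue free energies, no entropy terms).
* The dummy-site builder constructs and validates geometry; it does not
  produce bonded parameters for any MD engine, and no dynamics is run.
* Native energy formats of MD engines (Q, GROMACS, AMBER, NAMD) are not
  parsed; inputs use the package's documented delimited dialect.
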