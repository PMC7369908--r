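# tyrlie

Binding-affinity analysis for tyrosinase–ligand complexes with the linear
interaction energy (LIE) method, plus construction and geometric validation
of a Jahn–Teller-aware dummy-atom model for the active-site Cu²⁺ ions.

Tyrosinase (TYR) is the binuclear copper enzyme that initiates melanin
synthesis; its inhibitors (kojic acid and analogs, tropolone) are of broad
interest in medicine and cosmetics. This package is for computational
chemists who want to run, test, or teach the end-point free-energy analysis
of such metalloenzyme–ligand systems at desk scale: every input an MD engine
would provide can be generated synthetically, so the full pipeline runs in
seconds with no simulation software and no downloads.

## The model

The LIE estimator computes the binding free energy from the change in the
ligand's average interaction energies between the bound state (ligand in the
solvated protein) and the free state (ligand alone in solvent):

    ΔG_LIE = α (⟨V_vdw⟩_bound − ⟨V_vdw⟩_free) + β (⟨V_ele⟩_bound − ⟨V_ele⟩_free)

with α the non-polar scaling factor and β the polar factor, which depends on
ligand chemistry (hydroxyl count, net charge). Two parameterizations are
supported: the standard literature scheme (α = 0.181, β ∈ {0.50, 0.43, 0.37,
0.33}) and parameters calibrated by no-intercept least squares against
experimental affinities, which are themselves obtained from inhibition
constants via ΔG_exp = RT ln K_i. Per-residue/per-ion decomposition of the
bound-state energies identifies the binding determinants (the two copper
ions and Glu195 dominate the electrostatics), and the dummy-site module
builds a +2e Cu site as a core particle plus six charged dummies in a
distorted octahedron — elongated axial contacts being the geometric
signature of the Jahn–Teller effect in d⁹ Cu²⁺ coordination.

## Worked example

```r
library(tyrlie)

t4 <- table4_fixture()                       # packaged reference energies
cal <- calibrate_lie(t4, t4)
cal
#> <lie_calibration> 8 ligands: alpha = 0.197, beta = 0.343
#>   r^2 model 1 (literature) = 0.931; model 2 (fitted) = 0.944

lie_table(t4, ligands = t4)[4, ]             # kojic acid, literature scheme
#>   ligand_id alpha beta       dG     dG_sem
#> 4        KA 0.181 0.33 -7.04728 0.08701328
```

The calibration says that refitting the two scaling factors against the
eight experimentally characterized ligands gives α = 0.197, β = 0.343, and
that both parameterizations correlate strongly with experiment (r² of 0.93
and 0.94). The kojic-acid row shows the model-1 estimate, −7.05 kcal/mol,
against an experimental −7.44 kcal/mol from its 3.5 µM inhibition constant.

The `analysis/` scripts run the full workflow as a narrative:
`01_simulate.R` generates all synthetic inputs (energy series, decomposition
series, metal-site trajectories, a toy Cu site), `02_lie.R` computes the
per-ligand estimates, `03_calibrate.R` fits and cross-validates the
parameters, `04_decompose.R` ranks the per-residue contributions, and
`05_cudum.R` builds the dummy-site model and validates its coordination
geometry (Jahn–Teller scores ≈ 1.10 and 1.16 for the two ions, radial
distribution first peak at the coordination shell). Outputs land under
`results/`.

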