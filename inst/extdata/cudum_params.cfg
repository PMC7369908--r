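# Default dummy-site parameters for the octahedral Cu2+ dummy-atom model.
# PLACEHOLDER values: the published numeric charges and dummy bond lengths
# live in the original dummy-model force-field literature and are not restated
# here; every geometric and charge-conservation invariant the package
# enforces is independent of these numbers. Charges in elementary charge
# units, distances in Angstrom. Constraint: core + 4*eq + 2*ax = +2.0 e.
core_charge = 0.0
eq_charge = 0.32
ax_charge = 0.36
eq_distance = 0.9
ax_distance = 1.1
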