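# Mean per-residue interaction energies (kcal/mol) quoted in the source
# enzymology literature for the decomposition fixtures: the strong
# electrostatic Glu195 contact of the kojic-acid complex and the van der
# Waals contributions of active-site residues to the natural substrates.
ligand_id,residue,component,mean_energy
KA,Glu195,electrostatic,-12.45
l-DOPA,His204,vdw,-1.54
l-DOPA,Asn205,vdw,-3.86
l-DOPA,His208,vdw,-4.12
l-DOPA,Val218,vdw,-3.45
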