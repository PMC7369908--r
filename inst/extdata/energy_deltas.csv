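# Reference bound-minus-free ligand-surrounding interaction-energy
# differences (kcal/mol) for the nine tyrosinase systems, with the published
# LIE model-1/model-2 estimates and experimental binding free energies for
# comparison. sems are the published +/- values (uncertainty convention of
# the source data; not reproduced by this package's own block averaging).
ligand_id,dV_vdw,dV_vdw_sem,dV_ele,dV_ele_sem,dG_lie1_ref,dG_lie2_ref,dG_exp_ref
l-DOPA,-17.95,0.53,-22.93,1.02,-10.79,-11.20,NA
l-Tyr,-12.44,0.37,-20.91,0.82,-9.13,-9.47,-9.50
TRO,-12.9,0.19,-15.16,0.97,-7.93,-7.60,-8.30
KA,-5.68,0.08,-18.24,0.26,-7.04,-7.28,-7.46
KA1,-8.76,0.30,-11.32,0.53,-5.31,-5.51,-5.99
KA2,-12.91,0.03,-11.68,0.12,-6.17,-6.42,-5.85
KA3,-6.09,0.44,-14.19,0.18,-6.34,-5.98,-5.73
KA4,-16.68,0.05,-5.56,0.10,-4.83,-5.05,-5.24
KA5,-17.14,0.10,-3.75,0.08,-4.69,-4.53,-4.68
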