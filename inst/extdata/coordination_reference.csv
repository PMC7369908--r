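# Crystallographic and mean simulated coordination distances (Angstrom)
# between the two active-site Cu2+ ions of Bacillus megaterium tyrosinase
# and their His/water partners in the kojic-acid complex. "axial" marks the
# Jahn-Teller-elongated partner of each ion. Water experimental values are
# the canonical equatorial/axial Cu-O distances.
partner,atom,ion,class,axial,exp_dist,sim_mean,sim_sd
His204,NE2,Cu_A,protein,0,2.09,2.15,0.07
His208,NE2,Cu_A,protein,1,2.07,2.30,0.07
His231,NE2,Cu_A,protein,0,2.02,2.02,0.11
WT572,O,Cu_A,water,1,2.28,2.34,0.07
WT613,O,Cu_A,water,0,1.96,2.11,0.04
WT657,O,Cu_A,water,0,1.96,2.12,0.03
His42,NE2,Cu_B,protein,0,2.09,2.00,0.09
His60,NE2,Cu_B,protein,1,2.07,2.33,0.06
His69,NE2,Cu_B,protein,0,2.02,2.01,0.10
WT610,O,Cu_B,water,0,1.96,2.11,0.03
WT646,O,Cu_B,water,0,1.96,2.12,0.03
WT653,O,Cu_B,water,1,2.28,2.26,0.06
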