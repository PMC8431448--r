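compound,formula,mw,logp,logs,hbd,hba,aromatic_rings,rotatable_bonds,tpsa,flexibility,synthetic_note
dmso,C2H6OS,78.13,-1.3,1.1,0,1,0,0,17.1,0.05,continuous descriptors are synthetic placeholders
acetone,C3H6O,58.08,-0.2,0.9,0,1,0,0,17.1,0.08,continuous descriptors are synthetic placeholders
thiophane_oxide,C4H8OS,104.17,-0.8,0.6,0,1,0,0,17.1,0.04,continuous descriptors are synthetic placeholders
sulfolane,C4H8O2S,120.17,-0.7,0.5,0,2,0,0,34.1,0.04,continuous descriptors are synthetic placeholders
usafdo38,C4H8O3S,136.16,-1.1,0.4,0,3,0,0,43.4,0.03,continuous descriptors are synthetic placeholders
tmao,C3H9NO,75.11,-1.6,1.2,0,1,0,0,20.3,0.06,continuous descriptors are synthetic placeholders
dca,C24H40O4,392.58,3.5,-3.9,3,4,0,4,77.8,0.24,continuous descriptors are synthetic placeholders
udca,C24H40O4,392.58,3.1,-3.7,3,4,0,4,77.8,0.24,continuous descriptors are synthetic placeholders
diphenyl_sulfoxide,C12H10OS,202.27,2.1,-2.4,0,1,2,2,17.1,0.18,continuous descriptors are synthetic placeholders
benzophenone,C13H10O,182.22,3.2,-3.1,0,1,2,2,17.1,0.17,continuous descriptors are synthetic placeholders
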