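# Output phenotypes, kept outside the dynamical model and evaluated on the
# returned attractors. The two trigger-specific apoptosis levels are merged:
# only the cell fate matters here.
Proliferation = CyclinE1 | CyclinA
GrowthArrest = p21CIP | RB1 | RBL2
Apoptosis = TP53 | E2F1_lvl2
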