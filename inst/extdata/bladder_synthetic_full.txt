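# SYNTHETIC RECONSTRUCTION of a published logic-based model of bladder
# tumorigenesis (growth-factor signalling, CDKN2A products, cell-cycle
# regulators), before input injection: the four input parameters are kept as
# self-equations. Ternary variables (ATM, CHEK1/2, E2F1, E2F3) are encoded as
# exact-level Boolean pairs: V_lvl1 means level 1 exactly, V_lvl2 level 2.
# The reconstruction is validated against the attractor landscape the
# original model is documented to produce under the standard input
# configuration; it is a stand-in, not the original equation file.
AKT = PI3K
ATM_lvl1 = DNAdamage & !E2F1_lvl2
ATM_lvl2 = DNAdamage & E2F1_lvl2
CDC25A = (E2F1_lvl1 | E2F1_lvl2 | E2F3_lvl1 | E2F3_lvl2) & !CHEK1_2_lvl1 & !CHEK1_2_lvl2 & !RBL2
CHEK1_2_lvl1 = (ATM_lvl1 | ATM_lvl2) & !E2F1_lvl2
CHEK1_2_lvl2 = (ATM_lvl1 | ATM_lvl2) & E2F1_lvl2
CyclinA = CDC25A & (E2F1_lvl1 | E2F1_lvl2 | E2F3_lvl1 | E2F3_lvl2) & !p21CIP & !RBL2
CyclinD1 = (RAS | AKT) & !p16INK4a & !p21CIP
CyclinE1 = CDC25A & (E2F1_lvl1 | E2F1_lvl2 | E2F3_lvl1 | E2F3_lvl2) & !p21CIP & !RBL2
E2F1_lvl1 = (RAS | E2F3_lvl1 | E2F3_lvl2) & !RB1 & !RBL2 & !(E2F3_lvl2 & ATM_lvl2 & CHEK1_2_lvl2)
E2F1_lvl2 = E2F3_lvl2 & ATM_lvl2 & CHEK1_2_lvl2 & !RB1 & !RBL2
E2F3_lvl1 = RAS & !RB1 & !CHEK1_2_lvl2
E2F3_lvl2 = RAS & !RB1 & CHEK1_2_lvl2
EGFR = (EGFRstimulus | SPRY) & !FGFR3 & !GRB2
FGFR3 = FGFR3stimulus & !EGFR & !GRB2
GRB2 = EGFR | (FGFR3 & !SPRY)
MDM2 = (TP53 | AKT) & !p14ARF & !ATM_lvl1 & !ATM_lvl2
p14ARF = E2F1_lvl1 | E2F1_lvl2
p16INK4a = GrowthInhibitors & !RB1
p21CIP = (GrowthInhibitors | TP53) & !CyclinE1 & !AKT
PI3K = GRB2 & RAS & !PTEN
PTEN = TP53
RAS = EGFR | FGFR3 | GRB2
RB1 = !CyclinD1 & !CyclinE1 & !CyclinA & !p16INK4a
RBL2 = !CyclinD1 & !CyclinE1
SPRY = RAS
TP53 = ((ATM_lvl1 | ATM_lvl2) & (CHEK1_2_lvl1 | CHEK1_2_lvl2) | E2F1_lvl2) & !MDM2
DNAdamage = DNAdamage
EGFRstimulus = EGFRstimulus
FGFR3stimulus = FGFR3stimulus
GrowthInhibitors = GrowthInhibitors
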