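# SYNTHETIC RECONSTRUCTION of the 27-equation bladder-tumorigenesis working
# model: the input parameters (EGFRstimulus=1, FGFR3stimulus=1,
# GrowthInhibitors=1, DNAdamage=0) are injected directly into the concerned
# equations, so no equations are dedicated to them. See
# bladder_synthetic_full.txt for the pre-injection model; this file is a
# stand-in for the original supplementary equation file, not a copy of it.
AKT = PI3K
ATM_lvl1 = 0
ATM_lvl2 = 0
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
EGFR = !FGFR3 & !GRB2
FGFR3 = !EGFR & !GRB2
GRB2 = EGFR | (FGFR3 & !SPRY)
MDM2 = (TP53 | AKT) & !p14ARF & !ATM_lvl1 & !ATM_lvl2
p14ARF = E2F1_lvl1 | E2F1_lvl2
p16INK4a = !RB1
p21CIP = !CyclinE1 & !AKT
PI3K = GRB2 & RAS & !PTEN
PTEN = TP53
RAS = EGFR | FGFR3 | GRB2
RB1 = !CyclinD1 & !CyclinE1 & !CyclinA & !p16INK4a
RBL2 = !CyclinD1 & !CyclinE1
SPRY = RAS
TP53 = ((ATM_lvl1 | ATM_lvl2) & (CHEK1_2_lvl1 | CHEK1_2_lvl2) | E2F1_lvl2) & !MDM2
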