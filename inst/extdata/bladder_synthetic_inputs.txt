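# Input configuration: undamaged cells receiving both growth-stimulating and
# growth-inhibiting signals.
EGFRstimulus = 1
FGFR3stimulus = 1
GrowthInhibitors = 1
DNAdamage = 0
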