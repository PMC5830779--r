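# Pathological disturbance: deletion of the CDKN2A locus, whose gene
# products are the growth inhibitors p14ARF and p16INK4a.
p14ARF = 0
p16INK4a = 0
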