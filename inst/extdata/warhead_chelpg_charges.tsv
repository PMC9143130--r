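# Gas-phase ChelpG partial charges on the beta-lactone carbonyl carbon
# (C1) of the two inhibitor warheads, M06-2X/6-31+G(d,p); literature
# values used as input data.
inhibitor	charge_c1
hSalA	0.717
hBelC	0.637
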