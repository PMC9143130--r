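# Printed relative free energies (kcal/mol) of the stationary points of
# the two free-energy surfaces for covalent inhibition of the proteasome
# beta5 subunit by hBelC; literature values used as input data.
segment	order	label	type	G
1	1	E.I	minimum	0.0
1	2	TS1	saddle	24.9
1	3	E-I2	minimum	1.9
2	1	E-I2	minimum	1.9
2	2	TS3	saddle	21.0
2	3	E-PC	minimum	-15.6
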