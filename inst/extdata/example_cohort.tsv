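ID	Symbol	P_T1	FC_T1	P_T2	FC_T2	P_T3	FC_T3
g1	Actb	0.001	2	0.002	3	0.004	4
g2	Tnf	0.003	5	0.001	4	0.002	3
g3	Il6	0.01	2.5	0.2	1.1	0.01	-2.8
g4	Gapdh	0.5	1.2	0.6	-1.1	0.4	1.3
g5	Ccl2	0.02	-3	0.01	-2.2	0.03	-2.5
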