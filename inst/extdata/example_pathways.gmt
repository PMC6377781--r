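INFLAMMATION_A	synthetic demo set	Tnf	Il6	Ccl2	Il1b	Cxcl1	Ccl5	Cxcl2	Il1a	Tlr4	Nfkb1
INFLAMMATION_B	synthetic demo set	Tnf	Il6	Ccl2	Il1b	Cxcl1	Ccl5	Cxcl2	Il1a	Tlr4	Ptgs2
HOUSEKEEPING	synthetic demo set	Actb	Gapdh	Tuba1a	Rpl13
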