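# alginseq 0.1.0
sequence	molar_fraction
ΔGGMM	0.467
ΔMGMM	0.133
ΔGMMM	0.311
ΔMMMM	0.089
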