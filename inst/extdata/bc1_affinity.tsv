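variant	kd_um
Wild-type	21.4
b-G50A	4.62
b-A97L	2.69
b-G50A+A51E	1.91
b-G50A+A51E+A97L	0.91
a-S53W+b-G50A+A51E	0.4
a-S53W+b-G50A+A51E+A97L	0.14
b-G50A+A51I+G52Q+I53T	0.015
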