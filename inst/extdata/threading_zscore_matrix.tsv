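label	I-TASSER	MUSTER	QUARK	Pro-sp3	Chunk-TASSER	Phf19
I-TASSER	6.35	3.29	3.7	4.42	2.3	1.24
MUSTER	3.29	6.35	3.07	3.07	1.99	1.99
QUARK	3.7	3.07	6.35	3.7	3.29	0.73
Pro-sp3	4.42	3.07	3.7	6.35	2.3	1.24
Chunk-TASSER	2.3	1.99	3.29	2.3	6.35	1.64
Phf19	1.24	1.99	0.73	1.24	1.64	5.6
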