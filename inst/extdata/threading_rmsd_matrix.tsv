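label	I-TASSER	MUSTER	QUARK	Pro-sp3	Chunk-TASSER	Phf19
I-TASSER	0	4.99	4.16	5.16	4.76	8.09
MUSTER	4.99	0	4.64	6.08	6.35	6.67
QUARK	4.16	4.64	0	4.71	6.79	5.17
Pro-sp3	5.16	6.08	4.71	0	4.88	5.33
Chunk-TASSER	4.76	6.35	6.79	4.88	0	8.37
Phf19	8.09	6.67	5.17	5.33	8.37	0
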