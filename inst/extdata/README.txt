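Reference pairwise comparison matrices for five published NUPR1a structural
models (threading / ab-initio predictors I-TASSER, MUSTER, QUARK, Pro-sp3,
Chunk-TASSER) against each other and against the unrelated all-beta negative
control Phf19 (PDB 4BD3): C-alpha RMSD (Angstrom) and structural-alignment
Z-scores. Inputs to the consensus-statistics and ranking stage; see
load_reference_scores().
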