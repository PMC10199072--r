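# Salt / solvent fragment drop list used by parent-structure extraction.
# One canonical SMILES per line; '#' starts a comment. Edit to extend.
# halide anions
[F-]
[Cl-]
[Br-]
[I-]
# alkali / alkaline-earth cations and ammonium
[Li+]
[Na+]
[K+]
[Mg+2]
[Ca+2]
[NH4+]
# water and common solvents / counter-acids
O
CO
CCO
CC(=O)O
O=C(O)C(F)(F)F
Cl
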