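# Effector-associated amino-acid motifs shipped with the package.
# Patterns use fixed residues, bracketed residue classes and X for any residue.
"[YFW]XC": "[YFW]XC"
"[LI]XAR": "[LI]XAR"
"RXLR": "RXLR"
"CHXC": "CHXC"
"KECXD": "KECXD"
"YXSL[RK]": "YXSL[RK]"
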