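# Residue/bead naming for MARTINI-style coarse-grained membranes.
# `species` is the canonical species label used throughout the analyses;
# `head_bead` names the single reference bead tracked per lipid molecule
# (phosphate for phospholipids and sphingomyelin, hydroxyl for cholesterol).
lipids:
  POPC: {species: POPC, head_bead: PO4}
  POPS: {species: POPS, head_bead: PO4}
  POPE: {species: POPE, head_bead: PO4}
  PSM:  {species: SM,   head_bead: PO4}
  DPSM: {species: SM,   head_bead: PO4}
  CHOL: {species: CHOL, head_bead: ROH}
protein:
  residues: [PROT, ALA, ARG, ASN, ASP, CYS, GLN, GLU, GLY, HIS, ILE,
             LEU, LYS, MET, PHE, PRO, SER, THR, TRP, TYR, VAL]
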