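# Anchor definitions for the activation-state metrics.
#
# Residue numbers use author numbering of the target structure.  The
# clamp-twist dihedral spans the ArpC2/ArpC4 clamp; the alternate set
# applies to metazoan complexes whose ArpC2 numbering is shifted.
clamp_twist:
  human:
    - {subunit: ArpC2, resno: 18, resid: LYS, atom: CA}
    - {subunit: ArpC2, resno: 244, resid: ILE, atom: CA}
    - {subunit: ArpC4, resno: 147, resid: SER, atom: CA}
    - {subunit: ArpC4, resno: 32, resid: ARG, atom: CA}
  metazoan_alt:
    - {subunit: ArpC2, resno: 18, resid: ARG, atom: CA}
    - {subunit: ArpC2, resno: 262, resid: ILE, atom: CA}
    - {subunit: ArpC4, resno: 147, resid: SER, atom: CA}
    - {subunit: ArpC4, resno: 32, resid: ARG, atom: CA}
arpc4_bend:
  default:
    - {subunit: ArpC4, resno: 130, resid: LYS, atom: CA}
    - {subunit: ArpC4, resno: 141, resid: GLU, atom: CA}
    - {subunit: ArpC4, resno: 163, resid: GLU, atom: CA}
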