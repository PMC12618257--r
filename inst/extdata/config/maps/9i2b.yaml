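# Subunit map template for the SPIN90-Arp2/3 bidirectional-filament
# model (two asymmetric copies related by C2 symmetry).
#
# The chain layout below is a TEMPLATE: the deposition does not print
# its chain assignment, so verify_anchors is on and load_map() will
# refuse the map unless the clamp/bend anchor residues check out on the
# mapped chains.  Use infer_subunit_map() on the downloaded file to
# propose corrected chain ids, then edit this file.
verify_anchors: true
copies:
  copy1:
    SPIN90: A
    Arp3: B
    Arp2: C
    ArpC1: D
    ArpC2: E
    ArpC3: F
    ArpC4: G
    ArpC5: H
    Ac1: I
    Ac2: J
  copy2:
    SPIN90*: K
    Arp3: L
    Arp2: M
    ArpC1: N
    ArpC2: O
    ArpC3: P
    ArpC4: Q
    ArpC5: R
    Ac1: S
    Ac2: T
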