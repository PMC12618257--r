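# Subunit map template for the SPIN90-ARD / inactive bovine Arp2/3
# cocrystal.  Chain ids follow the common crystallographic Arp2/3
# convention; verify_anchors is on so a wrong layout fails loudly.
verify_anchors: true
copies:
  copy1:
    Arp3: A
    Arp2: B
    ArpC1: C
    ArpC2: D
    ArpC3: E
    ArpC4: F
    ArpC5: G
    SPIN90: H
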