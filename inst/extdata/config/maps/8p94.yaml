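# Subunit map template for the cortactin-bound branch junction
# (Arp2/3 on a mother filament, MA1-MA6, with daughter subunits).
# Chain ids are a template; verify against the deposited file with
# infer_subunit_map() before a reproduction run.
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
    MA1: H
    MA2: I
    MA3: J
    MA4: K
    MA5: L
    MA6: M
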