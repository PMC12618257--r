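# Subunit map template for the SPIN90-ARD crystal structure.
verify_anchors: false
copies:
  copy1:
    SPIN90: A
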