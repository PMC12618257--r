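# Actin-fold subdomain residue ranges used for the flattening dihedral
# (center-of-mass dihedral over subdomains 2,1,3,4).
#
# The actin ranges follow the conventional division of the actin fold
# (subdomains 1/3 barbed-end lobes, 2/4 pointed-end lobes; Kabsch et al.
# numbering).  The Arp3 and Arp2 ranges map that division onto the human
# subunits via their structural correspondence with actin.  These
# boundaries are data, not code: edit this file to explore boundary
# sensitivity.
actin:
  "1": [[1, 32], [70, 144], [338, 375]]
  "2": [[33, 69]]
  "3": [[145, 180], [270, 337]]
  "4": [[181, 269]]
Arp3:
  "1": [[5, 33], [77, 153], [375, 418]]
  "2": [[34, 76]]
  "3": [[154, 189], [282, 374]]
  "4": [[190, 281]]
Arp2:
  "1": [[6, 34], [66, 141], [334, 380]]
  "2": [[35, 65]]
  "3": [[142, 177], [267, 333]]
  "4": [[178, 266]]
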