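# Tag map for the synthetic HPbCD topology (same content as the embedded
# [ tags ] section; bundled as a worked example of the YAML format).
tags:
  glucopyranose_hydroxyl_O: [O3, O6]
  glucopyranose_hydroxyl_H: [HO3, HO6]
  hydroxypropyl_hydroxyl_O: [O8]
  hydroxypropyl_hydroxyl_H: [HO8]
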