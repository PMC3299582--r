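# Default macro-category scheme for HVS-I haplogroup labels.
# Longest-prefix match; labels matching no prefix fall into `default`.
prefixes:
  L0a: L0a
  L1b: L1b
  L1c: L1c
  L2a: L2a
  L2b: L2b
  L2c: L2c
  L3b: L3b
  L3d: L3d
  L3e: L3e
  L3f: L3f
  L0: "Other L0'1'2"
  L1: "Other L0'1'2"
  L2: "Other L0'1'2"
  L5: "Other L0'1'2"
  L3: "Other L3"
  L4: "Other L3"
  U6: U6
default: non-L/U6
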