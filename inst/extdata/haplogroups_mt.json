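{
  "marker_kind": "mt",
  "comment": "mtDNA haplogroup prefix -> continent of highest frequency, as used in the built-in casework table. U6a -> Europe and R0 -> 'South Asian' reproduce the source annotations verbatim even though both are phylogeographically debatable; edit this file to override.",
  "entries": {
    "H": "Europe",
    "H1": "Europe",
    "H1b": "Europe",
    "H41a": "Europe",
    "J2b": "Europe",
    "K1a": "Europe",
    "L2a": "Africa/Africa America",
    "L2b": "Africa/Africa America",
    "L3e": "Africa/Africa America",
    "M1a": "South Asia",
    "M5a": "South Asia",
    "R0": "South Asian",
    "R9c": "South Asia",
    "T1a": "Europe",
    "T2": "Europe",
    "T2e": "Europe",
    "U4b": "Europe",
    "U5a": "Europe",
    "U6a": "Europe"
  }
}
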