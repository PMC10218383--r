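{
  "marker_kind": "Y",
  "comment": "Y haplogroup prefix -> region of highest predictor-assigned frequency, as used in the built-in casework table.",
  "entries": {
    "E1b1b >V13": "Europe, the Near East, and northern Africa",
    "E1b1b L67": "Europe, the Near East, and northern Africa",
    "I2a1b3": "south-eastern, south-western, north-western Europe",
    "J2a1 M67": "Europe, the Middle East and northern Africa",
    "R1b": "western Europe",
    "R1b M269": "western Europe"
  }
}
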