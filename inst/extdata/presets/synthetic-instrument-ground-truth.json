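{
  "pattern": "instrument",
  "p_do_control": 0.35,
  "p_do_treated": 0.75,
  "ace": -0.4
}
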