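{
  "pattern": "frontdoor",
  "p_do_control": 0.45,
  "p_do_treated": 0.675,
  "ace": -0.225
}
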