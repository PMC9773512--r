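{
  "pattern": "confounder",
  "p_do_control": 0.28,
  "p_do_treated": 0.58,
  "ace": -0.3
}
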