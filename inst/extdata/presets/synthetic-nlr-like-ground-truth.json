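{
  "pattern": "nlr_like",
  "p_do_control": 0.6036,
  "p_do_treated": 0.5524,
  "ace": 0.0512
}
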