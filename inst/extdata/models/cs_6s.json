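{
  "name": "cs_6s",
  "epoch_kind": "fixed6s",
  "intercept": 7.929,
  "coef_mad": 0.033,
  "training_label": "constant-speed walking test, fixed 6 s epochs",
  "p_values": {"intercept": 0.001, "coef_mad": 0.001}
}
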