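{
  "name": "cs_float",
  "epoch_kind": "floating",
  "intercept": 7.186,
  "coef_mad": 0.033,
  "coef_dmad": 0.068,
  "coef_expfs": -0.004,
  "training_label": "constant-speed walking test, floating epochs",
  "p_values": {"intercept": 0.001, "coef_mad": 0.001, "coef_dmad": 0.049, "coef_expfs": 0.986}
}
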