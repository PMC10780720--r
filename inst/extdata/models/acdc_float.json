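{
  "name": "acdc_float",
  "epoch_kind": "floating",
  "intercept": -3.160,
  "coef_mad": 0.005,
  "coef_dmad": 0.218,
  "coef_expfs": 2.004,
  "training_label": "acceleration/deceleration walking test, floating epochs",
  "p_values": {"intercept": 0.295, "coef_mad": 0.585, "coef_dmad": 0.008, "coef_expfs": 0.001}
}
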