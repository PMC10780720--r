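{
  "name": "acdc_6s",
  "epoch_kind": "fixed6s",
  "intercept": 10.379,
  "coef_mad": 0.036,
  "training_label": "acceleration/deceleration walking test, fixed 6 s epochs",
  "p_values": {"intercept": 0.002, "coef_mad": 0.001}
}
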