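passive:
  healthy:
    c_scale: 359.0
    b: [67.07, 24.16, 21.60]
    density: 1370.0
  infarcted:
    c_scale: 359.0
    b: [46.80, 22.00, 18.00]
    density: 1370.0
  implanted:
    c_scale: 359.0
    b: [53.40, 22.00, 18.00]
    density: 1370.0
  patch:
    c_scale: 359.0
    b: [50.00, 50.00, 21.60]
    density: 1370.0
active:
  t_max: 135700.0
  l0: 1.58
  lR: 1.91
  big_b: 4.75
  m_slope: 1.049
  b_intercept: -1.429
  ca0: 4.35
  ca0_max: 4.35
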