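TPA
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 10  0  0  0  0  0  0  0  0  0999 V2000
   -3.2231    0.7625    0.9310 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0658   -0.0697    0.6021 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0077   -0.7534   -0.7281 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0679    0.3947   -0.4381 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4069    0.1335   -0.2407 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1677   -0.5309   -1.2173 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5354   -0.7605   -1.0452 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.1744   -0.3216    0.1106 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4467    0.3483    1.0896 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0793    0.5747    0.9113 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
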