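TT4
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 13  0  0  0  0  0  0  0  0  0999 V2000
    3.7612   -0.5141   -1.5442 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.6734   -0.4236   -0.7826 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8186   -0.5067    0.5597 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.5895   -0.4052    1.0035 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2298   -0.5853    2.2984 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.7238   -0.1638   -0.0714 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6684    0.1339   -0.1009 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3702    0.5096    1.0518 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7379    0.7930    0.9808 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4110    0.7124   -0.2367 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7175    0.3595   -1.3914 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3511    0.0773   -1.3278 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4390   -0.2444   -1.2262 N   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
TT4
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 13  0  0  0  0  0  0  0  0  0999 V2000
    3.9456    1.1065    0.0577 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.7784    0.4678    0.0209 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7790   -0.8809    0.1243 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.5089   -1.1916    0.0337 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0398   -2.4602   -0.0619 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.7449   -0.0186   -0.0258 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6652    0.1794   -0.0124 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5532   -0.8418    0.3496 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9320   -0.6071    0.3491 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4326    0.6449   -0.0027 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5566    1.6719   -0.3444 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1785    1.4448   -0.3438 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5923    1.0436   -0.0981 N   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
TT4
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 13  0  0  0  0  0  0  0  0  0999 V2000
    3.9784   -0.3661    0.9131 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.7583    0.0432    0.5733 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5348    1.3720    0.4548 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.2751    1.4360    0.0982 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6478    2.5766   -0.2812 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.7239    0.1478    0.0997 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6149   -0.2954   -0.0971 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7006    0.5891   -0.0637 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0009    0.1138   -0.2627 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2275   -1.2427   -0.4871 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1565   -2.1325   -0.5020 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8559   -1.6646   -0.3018 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7196   -0.7459    0.3475 N   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
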