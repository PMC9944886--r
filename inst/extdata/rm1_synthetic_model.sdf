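RM1
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 11  0  0  0  0  0  0  0  0  0999 V2000
   -3.2307   -0.7539    0.3015 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8272   -1.0859    0.1147 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9443    0.0306    0.4404 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0461    1.2225   -0.5390 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3175    1.9268   -0.5023 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2287    0.7694   -0.2387 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6005    0.7074   -0.4180 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.2615   -0.4717   -0.0672 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5516   -1.5588    0.4661 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1702   -1.4816    0.6559 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5157   -0.3145    0.2916 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
RM1
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 11  0  0  0  0  0  0  0  0  0999 V2000
    2.6636   -1.4919   -0.7704 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0353   -0.7450    0.3116 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.0897    0.2506   -0.1896 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0045    1.4624    0.7686 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3648    2.1050    0.5151 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1812    0.8947    0.1843 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5616    0.7770    0.1977 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1243   -0.4480   -0.1622 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3075   -1.5256   -0.5350 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9163   -1.3919   -0.5586 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3564   -0.1764   -0.1956 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
RM1
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 11  0  0  0  0  0  0  0  0  0999 V2000
    2.6276   -0.5204    0.7251 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3053    0.1130   -0.5447 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.9828    0.7310   -0.6219 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6566    1.7890    0.4558 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8759    1.8853    0.4920 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2640    0.4814    0.1380 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4930   -0.1292    0.3246 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6571   -1.4389   -0.1295 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6059   -2.1093   -0.7735 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3738   -1.4807   -0.9703 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2064   -0.1874   -0.4970 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
RM1
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 11  0  0  0  0  0  0  0  0  0999 V2000
    2.1943    1.8652   -0.2211 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9613    0.4775   -0.5949 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.1837   -0.2555    0.4098 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1117   -1.7516    0.0171 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0965   -1.9026   -0.9184 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0102   -0.8607   -0.3540 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3798   -0.7460   -0.5237 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0367    0.3170    0.0987 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3219    1.2457    0.8708 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9384    1.1283    1.0256 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2875    0.0750    0.4004 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
RM1
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 11  0  0  0  0  0  0  0  0  0999 V2000
   -1.1715    1.6962   -2.5250 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3070    1.3224   -1.4146 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6223   -0.0135   -0.9051 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8096   -0.0052    0.0842 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2288    0.3030    1.4722 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1237   -0.3266    1.3566 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9948   -0.6752    2.3746 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2301   -1.2271    2.0284 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5803   -1.4118    0.6814 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7005   -1.0448   -0.3395 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4726   -0.5031    0.0111 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
RM1
  model-built synthetic geometry (ETKDG/MMFF), not a crystallographic pose

 11  0  0  0  0  0  0  0  0  0999 V2000
   -2.4570    1.4169    0.5461 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0734    0.0249    0.3592 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0649   -0.1471   -0.6919 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8254   -1.6574   -0.9360 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2519   -2.0988    0.0650 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0689   -0.8485    0.1553 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3698   -0.7115    0.6100 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9401    0.5628    0.6090 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2077    1.6736    0.1628 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8915    1.5268   -0.2823 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3253    0.2605   -0.2737 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$$$$
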