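G: 5.0
nmda_fraction: 0.2
R: 125.0
R0: 75.0
dt: 0.1
Mg: 1.0
fractions:
  VIP1: 0.02
  E23: 0.238
  PV23: 0.0168
  SST23: 0.0126
  VIP23: 0.0126
  E4: 0.2125
  PV4: 0.020625
  SST4: 0.013125
  VIP4: 0.00375
  E5: 0.1445
  PV5: 0.01275
  SST5: 0.0102
  VIP5: 0.00255
  E6: 0.238
  PV6: 0.0231
  SST6: 0.0168
  VIP6: 0.0021
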