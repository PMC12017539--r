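"group","V_rest","V_th","C_m","g_L","tau_ref","nu_bg"
"VIP1",-68,-42,70,4.4,1,1100
"E23",-75,-50,180,9,2,1950
"PV23",-72,-48,90,9,1,2000
"SST23",-65,-45,110,5.5,2,1000
"VIP23",-68,-42,70,4.4,1,1100
"E4",-75,-50,180,9,2,1950
"PV4",-72,-48,90,9,1,2000
"SST4",-65,-45,110,5.5,2,1000
"VIP4",-68,-42,70,4.4,1,1100
"E5",-75,-50,180,9,2,1950
"PV5",-72,-48,90,9,1,2000
"SST5",-65,-45,110,5.5,2,1000
"VIP5",-68,-42,70,4.4,1,1100
"E6",-75,-50,180,9,2,1950
"PV6",-72,-48,90,9,1,2000
"SST6",-65,-45,110,5.5,2,1000
"VIP6",-68,-42,70,4.4,1,1100
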