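"peak_id","mean_nrg","mean_rg","p_value"
"GP1",0.137,0.182,0.048
"GP2",0.623,0.828,0.075
"GP3",0.013,0.005,0.179
"GP4",22.58,27.448,0.003
"GP5",0.157,0.144,0.46
"GP6",6.588,7.577,0.042
"GP7",0.353,0.348,0.902
"GP8",20.344,19.628,0.264
"GP9",10.108,9.925,0.678
"GP10",6.424,6.097,0.446
"GP11",0.691,0.725,0.542
"GP12",1.005,0.82,0.276
"GP13",0.033,0.014,0.209
"GP14",15.783,12.944,0.007
"GP15",1.84,1.496,0.017
"GP16",2.313,2.255,0.657
"GP17",0.62,0.521,0.146
"GP18",7.218,5.976,0.028
"GP19",0.778,0.737,0.446
"GP20",0.027,0.011,0.168
"GP21",0.495,0.519,0.692
"GP22",0.003,0.002,0.622
"GP23",0.835,0.792,0.689
"GP24",1.033,1.006,0.859
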