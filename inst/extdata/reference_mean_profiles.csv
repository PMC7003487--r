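"sample_id","GP1","GP2","GP3","GP4","GP5","GP6","GP7","GP8","GP9","GP10","GP11","GP12","GP13","GP14","GP15","GP16","GP17","GP18","GP19","GP20","GP21","GP22","GP23","GP24"
"mean_nrg",0.137,0.623,0.013,22.58,0.157,6.588,0.353,20.344,10.108,6.424,0.691,1.005,0.033,15.783,1.84,2.313,0.62,7.218,0.778,0.027,0.495,0.003,0.835,1.033
"mean_rg",0.182,0.828,0.005,27.448,0.144,7.577,0.348,19.628,9.925,6.097,0.725,0.82,0.014,12.944,1.496,2.255,0.521,5.976,0.737,0.011,0.519,0.002,0.792,1.006
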