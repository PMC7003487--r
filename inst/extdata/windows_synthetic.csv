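"peak_id","start_min","end_min"
"GP1",1,2
"GP2",2,3
"GP3",3,4
"GP4",4,5
"GP5",5,6
"GP6",6,7
"GP7",7,8
"GP8",8,9
"GP9",9,10
"GP10",10,11
"GP11",11,12
"GP12",12,13
"GP13",13,14
"GP14",14,15
"GP15",15,16
"GP16",16,17
"GP17",17,18
"GP18",18,19
"GP19",19,20
"GP20",20,21
"GP21",21,22
"GP22",22,23
"GP23",23,24
"GP24",24,25
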