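"peak_id","composition","hex","hexnac","fuc","neuac","arm","galactose_count","sialyl_count","is_fucosylated","is_bisecting","is_neutral","is_oligomannose"
"GP1","H3N3F1",3,3,1,0,,0,0,TRUE,FALSE,TRUE,FALSE
"GP2","H3N4",3,4,0,0,,0,0,FALSE,FALSE,TRUE,FALSE
"GP3","H3N5",3,5,0,0,,0,0,FALSE,TRUE,TRUE,FALSE
"GP4","H3N4F1",3,4,1,0,,0,0,TRUE,FALSE,TRUE,FALSE
"GP5","H5N2",5,2,0,0,,,0,FALSE,FALSE,TRUE,TRUE
"GP6","H3N5F1",3,5,1,0,,0,0,TRUE,TRUE,TRUE,FALSE
"GP7","H4N4",4,4,0,0,,1,0,FALSE,FALSE,TRUE,FALSE
"GP8","H4N4F1(6)",4,4,1,0,"6",1,0,TRUE,FALSE,TRUE,FALSE
"GP9","H4N4F1(3)",4,4,1,0,"3",1,0,TRUE,FALSE,TRUE,FALSE
"GP10","H4N5F1(6)",4,5,1,0,"6",1,0,TRUE,TRUE,TRUE,FALSE
"GP11","H4N5F1(3)",4,5,1,0,"3",1,0,TRUE,TRUE,TRUE,FALSE
"GP12","H5N4",5,4,0,0,,2,0,FALSE,FALSE,TRUE,FALSE
"GP13","H5N5",5,5,0,0,,2,0,FALSE,TRUE,TRUE,FALSE
"GP14","H5N4F1",5,4,1,0,,2,0,TRUE,FALSE,TRUE,FALSE
"GP15","H5N5F1",5,5,1,0,,2,0,TRUE,TRUE,TRUE,FALSE
"GP16","H4N4F1S1(3)",4,4,1,1,"3",1,1,TRUE,FALSE,FALSE,FALSE
"GP17","H5N4S1",5,4,0,1,,2,1,FALSE,FALSE,FALSE,FALSE
"GP18","H5N4F1S1",5,4,1,1,,2,1,TRUE,FALSE,FALSE,FALSE
"GP19","H5N5F1S1",5,5,1,1,,2,1,TRUE,TRUE,FALSE,FALSE
"GP20","H5N4F2S1",5,4,2,1,,2,1,TRUE,FALSE,FALSE,FALSE
"GP21","H5N4S2",5,4,0,2,,2,2,FALSE,FALSE,FALSE,FALSE
"GP22","H5N5S2",5,5,0,2,,2,2,FALSE,TRUE,FALSE,FALSE
"GP23","H5N4F1S2",5,4,1,2,,2,2,TRUE,FALSE,FALSE,FALSE
"GP24","H5N5F1S2",5,5,1,2,,2,2,TRUE,TRUE,FALSE,FALSE
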