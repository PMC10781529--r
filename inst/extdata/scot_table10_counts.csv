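primer,tbn,mbn,pbn,ub,bsr_max,bsr_min
SCoT-1,7,3,4,1,835,175
SCoT-2,3,3,0,0,390,200
SCoT-6,3,2,1,0,530,300
SCoT-8,3,1,2,1,400,215
SCoT-9,11,4,7,1,1680,300
SCoT-11,7,3,4,0,1325,215
SCoT-12,4,2,2,1,500,210
SCoT-14,6,4,2,1,830,280
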