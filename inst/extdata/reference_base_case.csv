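scenario,strategy,total_cost,cost_pfd,lys,qalys
A,standard_care,17243,10055,0.221,0.109
A,olaparib,24626,12035,0.321,0.173
B,standard_care,55476,44261,0.540,0.313
B,olaparib,48526,32096,0.665,0.380
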