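scenario,delta_lys,delta_qalys,delta_cost,icer_label,inhb,inmb
A,0.100,0.063,7382,116903,0.01,2090
B,0.125,0.068,-6950,dominant,0.114,17109
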