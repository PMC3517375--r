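term,dimension,level,decrement
constant,any,2,0.081
decrement,mobility,2,0.069
decrement,mobility,3,0.314
decrement,self_care,2,0.104
decrement,self_care,3,0.214
decrement,usual_activities,2,0.036
decrement,usual_activities,3,0.094
decrement,pain_discomfort,2,0.123
decrement,pain_discomfort,3,0.386
decrement,anxiety_depression,2,0.071
decrement,anxiety_depression,3,0.236
n3,any,3,0.269
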