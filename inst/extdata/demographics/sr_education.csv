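level,low,moderate_high
elementary,0,8
junior_high,4,8
senior_high,17,30
college_plus,89,44
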