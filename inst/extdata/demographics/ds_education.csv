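level,none,low_moderate,high
elementary,0,2,6
junior_high,2,2,8
senior_high,12,6,29
college_plus,83,20,30
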