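level,none,low_moderate,high
unmarried,36,20,27
married,61,9,39
divorced,0,1,7
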