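group,mean,sd,n
none,44,17,97
low_moderate,38,19,30
high,47,18,73
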