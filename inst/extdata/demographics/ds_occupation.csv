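level,none,low_moderate,high
yes,64,13,33
no,33,17,40
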