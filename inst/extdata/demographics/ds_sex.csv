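level,none,low_moderate,high
male,29,9,21
female,68,21,52
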