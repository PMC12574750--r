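level,low,moderate_high
male,27,32
female,83,58
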