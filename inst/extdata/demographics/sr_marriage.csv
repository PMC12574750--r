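level,low,moderate_high
unmarried,34,49
married,75,34
divorced,1,7
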