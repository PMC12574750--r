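level,low,moderate_high
yes,69,41
no,41,49
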