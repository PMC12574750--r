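group,mean,sd,n
low,45,16.7,110
moderate_high,42,19.3,90
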