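n1,n0,q1
633,565,0.000497
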