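observed,predicted_control,predicted_case
control,440,125
case,232,401
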