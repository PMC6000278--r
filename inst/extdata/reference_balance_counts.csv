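characteristic,level,case,control
age_group,<50,125,136
age_group,>=50,508,429
province,guangdong,461,402
province,other,172,162
living_contact,no,527,481
living_contact,yes,106,84
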