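occupation,prestige
physician,86
professor,78
psychologist,74
engineer,71
architect,70
pharmacist,68
teacher,64
accountant,57
programmer,56
electrician,51
salesperson,36
secretary,33
cook,31
driver,30
attendant,28
cleaner,22
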