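word,role,polarity,dimension,source
man,target,advantaged,gender,illustrative
men,target,advantaged,gender,illustrative
he,target,advantaged,gender,illustrative
him,target,advantaged,gender,illustrative
male,target,advantaged,gender,illustrative
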