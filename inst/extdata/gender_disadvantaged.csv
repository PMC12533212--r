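word,role,polarity,dimension,source
woman,target,disadvantaged,gender,illustrative
women,target,disadvantaged,gender,illustrative
she,target,disadvantaged,gender,illustrative
her,target,disadvantaged,gender,illustrative
female,target,disadvantaged,gender,illustrative
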