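word,role,polarity,dimension,source
incompetent,attribute,low,competence,illustrative
unintelligent,attribute,low,competence,illustrative
incapable,attribute,low,competence,illustrative
clumsy,attribute,low,competence,illustrative
inefficient,attribute,low,competence,illustrative
foolish,attribute,low,competence,illustrative
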