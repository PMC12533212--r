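word,role,polarity,dimension,source
competent,attribute,high,competence,illustrative
intelligent,attribute,high,competence,illustrative
capable,attribute,high,competence,illustrative
skillful,attribute,high,competence,illustrative
efficient,attribute,high,competence,illustrative
clever,attribute,high,competence,illustrative
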