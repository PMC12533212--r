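word,role,polarity,dimension,source
warm,attribute,high,warmth,illustrative
friendly,attribute,high,warmth,illustrative
kind,attribute,high,warmth,illustrative
caring,attribute,high,warmth,illustrative
sincere,attribute,high,warmth,illustrative
trustworthy,attribute,high,warmth,illustrative
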