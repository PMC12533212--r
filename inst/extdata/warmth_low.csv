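word,role,polarity,dimension,source
cold,attribute,low,warmth,illustrative
unfriendly,attribute,low,warmth,illustrative
cruel,attribute,low,warmth,illustrative
indifferent,attribute,low,warmth,illustrative
insincere,attribute,low,warmth,illustrative
untrustworthy,attribute,low,warmth,illustrative
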