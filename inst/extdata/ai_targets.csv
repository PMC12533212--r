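word,role,polarity,dimension,source
artificial intelligence,target,none,,illustrative
robot,target,none,,illustrative
intelligent agent,target,none,,illustrative
ai agent,target,none,,illustrative
chatbot,target,none,,illustrative
machine learning,target,none,,illustrative
neural network,target,none,,illustrative
virtual assistant,target,none,,illustrative
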