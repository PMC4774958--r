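species,P10,P9,P8,P7,Alula3,gpc10
B. bubo,+,+,+,+,+,+
B. scandiacus,+,-,-,-,-,-
T. furcata,+,-,-,-,-,+
A. otus,+,+,-,-,-,-
A. flammeus,+,+,-,-,-,-
A. funereus,+,+,+,-,-,-
A. noctua,+,+,-,-,-,-
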