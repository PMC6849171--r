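modifier	grade
mild	2
slight	2
occasional	2
intermittent	2
noticeable	2
moderate	2
severe	3
significant	3
bad	3
constant	3
frequent	3
considerable	3
terrible	3
some	2
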