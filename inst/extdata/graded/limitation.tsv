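modifier	grade
slightly	2
somewhat	2
partly	2
completely	3
totally	3
severely	3
very	3
hugely	3
massively	3
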