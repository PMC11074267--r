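dataset	bin	count
train	1.0-2.0	62
train	2.0-3.0	2147
train	3.0-4.0	4443
validation	1.0-2.0	5
validation	2.0-3.0	222
validation	3.0-4.0	513
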