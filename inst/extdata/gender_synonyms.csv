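raw,canonical
f,F
female,F
femme,F
woman,F
m,M
male,M
homme,M
man,M
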