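keyword,stage
metasta,metastatic
adjuvant,early
early,early
precoce,early
locally advanced,locally_advanced
localement avance,locally_advanced
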