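raw,canonical
cr,CR
complete response,CR
reponse complete,CR
pr,PR
partial response,PR
reponse partielle,PR
sd,SD
stable disease,SD
maladie stable,SD
pd,PD
progressive disease,PD
progression,PD
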