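event_type,weight,terminal
REMI,0.2,FALSE
CHF,0.3,FALSE
SHK,0.5,FALSE
DTH,1,TRUE
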