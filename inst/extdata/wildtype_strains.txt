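Hm-105
Basel1
Basel2
reg-16
AEP1
AEP2
Ho_CS
Ho_CR
Nicolet
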