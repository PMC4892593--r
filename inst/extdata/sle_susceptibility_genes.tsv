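gene
IRF5
ITGAX
ITGAM
BLK
ETS1
CDKN1B
GHR
TYRO3
SOCS6
SEC61G
STAT4
IRF7
TNIP1
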