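DIO1
DIO2
DIO3
GPX1
GPX2
GPX3
GPX4
GPX6
MSRB1
SELENOF
SELENOH
SELENOI
SELENOK
SELENOM
SELENON
SELENOO
SELENOP
SELENOS
SELENOT
SELENOV
SELENOW
SEPHS2
TXNRD1
TXNRD2
TXNRD3
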