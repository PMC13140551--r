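binA	binB	98.6	930	1000
binB	binA	98.4	921	1000
binC	binD	99.1	955	1000
binD	binC	99.0	948	1000
binA	binA	100.0	1000	1000
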