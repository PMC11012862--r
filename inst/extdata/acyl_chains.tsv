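shorthand	note
14:0	reconstruction: exact published 24-chain list unavailable
15:0
16:0
16:1
17:0
18:0
18:1
19:0
20:0
20:1
21:0
22:0
22:1
23:0
24:0
24:1
25:0
26:0
26:1
27:0
28:0
28:1
29:0
30:0
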