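amount	target_fraction
8	0.0028
9	0.0076
10	0.0199
11	0.0501
12	0.113
13	0.21
14	0.307
15	0.3699
16	0.4001
17	0.4124
18	0.4172
19	0.419
20	0.4196
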