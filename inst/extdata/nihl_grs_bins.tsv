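bin	n_case	n_control
<=5	48	140
6	22	35
7	31	32
8	22	30
9	17	10
>=10	13	5
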