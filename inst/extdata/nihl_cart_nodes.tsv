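node_id	n_control	n_case
1	87	26
2	18	9
3	15	12
4	63	22
5	3	9
6	20	18
7	31	23
8	15	34
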