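subject	n_components	n_artifact	n_unlikely_artifact
1	97	43	54
2	75	29	46
3	81	31	50
4	105	45	60
5	57	30	27
6	122	50	72
7	80	29	51
8	161	56	105
9	154	51	103
10	108	49	59
11	285	78	207
12	99	44	55
13	120	50	70
14	106	44	62
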