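position	nucleotide	code
1	U	1
1	A	1
1	G	-1
1	C	-1
2	U	1
3	A	1
6	A	1
7	U	1
10	U	1
10	G	-1
13	A	1
13	G	-1
14	U	1
19	C	1
19	G	1
19	U	-1
19	A	-1
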