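1	rs00001	0	1000	A	T	A	A	A	A	A	A	A	T	A	T	A	T	A	T	A	T	T	T	A	T	A	T	A	A	A	T	A	A	A	A	A	T	A	A	T	T	A	T	A	A	A	T	A	T	A	A	A	A	T	T	A	A	A	T	A	A	T	T	A	A	A	A	A	T	A	T	A	T	A	A	A	A	A	T	A	A	A	T	A	A	A	T	A	A	T	T	A	A	A	A	A	T	A	T	A	A	A	A	A	T	A	T	T	T	A	T	A	A	A	T	A	T	A	T	A	T	A	A
1	rs00002	0	2000	T	T	A	T	A	A	A	T	A	T	A	A	A	T	A	A	A	T	T	T	T	T	A	T	T	T	A	T	A	T	A	A	A	T	T	T	T	T	A	T	A	T	A	A	A	A	A	T	T	T	A	T	A	A	A	T	A	A	A	T	T	T	A	A	A	A	A	A	T	T	A	T	A	A	A	T	A	T	A	T	A	T	T	T	A	A	A	T	A	T	T	T	T	T	T	T	A	A	A	A	A	A	A	A	A	T	A	T	A	T	A	A	A	A	A	T	A	T	A	T
1	rs00003	0	3000	A	T	A	T	A	A	A	T	A	A	A	A	A	T	A	A	T	T	A	T	A	A	A	A	A	T	A	T	A	A	A	A	A	T	A	A	A	A	A	A	A	A	A	A	A	A	A	T	T	T	A	T	A	T	A	A	A	A	A	A	A	A	A	A	A	T	A	T	A	T	A	T	A	T	A	T	T	T	A	A	T	T	A	A	A	A	A	T	A	T	A	A	A	T	A	A	A	T	A	A	A	A	T	T	A	A	A	A	A	A	A	T	A	A	A	A	T	T	A	A
1	rs00004	0	4000	A	T	A	T	T	T	A	T	A	A	A	T	A	A	A	T	A	T	A	A	A	A	A	T	A	A	A	A	A	A	A	A	A	A	A	T	A	A	T	T	A	A	A	A	A	A	T	T	A	T	A	A	A	T	A	T	A	T	A	A	A	A	A	T	T	T	A	T	T	T	A	A	A	T	A	T	A	T	A	T	A	T	A	T	A	A	A	A	A	A	A	T	A	T	A	T	A	T	T	T	A	T	A	T	T	T	A	A	A	A	A	A	A	T	A	A	A	A	A	T
1	rs00005	0	5000	A	T	A	A	A	A	A	A	A	A	A	T	A	T	A	T	A	A	A	A	A	A	A	A	A	T	T	T	A	A	A	A	A	A	A	A	A	A	A	T	A	T	A	T	A	A	A	T	A	A	A	A	A	A	A	T	A	A	A	T	A	A	A	T	A	T	A	T	A	T	A	A	A	A	A	A	A	A	A	T	A	A	A	A	A	A	A	A	A	A	A	A	A	T	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	A	T	A	T	A	A	A	A	A	A
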