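sample0001	sample0001	0	0	0	-9
sample0002	sample0002	0	0	0	-9
sample0003	sample0003	0	0	0	-9
sample0004	sample0004	0	0	0	-9
sample0005	sample0005	0	0	0	-9
sample0006	sample0006	0	0	0	-9
sample0007	sample0007	0	0	0	-9
sample0008	sample0008	0	0	0	-9
sample0009	sample0009	0	0	0	-9
sample0010	sample0010	0	0	0	-9
sample0011	sample0011	0	0	0	-9
sample0012	sample0012	0	0	0	-9
sample0013	sample0013	0	0	0	-9
sample0014	sample0014	0	0	0	-9
sample0015	sample0015	0	0	0	-9
sample0016	sample0016	0	0	0	-9
sample0017	sample0017	0	0	0	-9
sample0018	sample0018	0	0	0	-9
sample0019	sample0019	0	0	0	-9
sample0020	sample0020	0	0	0	-9
sample0021	sample0021	0	0	0	-9
sample0022	sample0022	0	0	0	-9
sample0023	sample0023	0	0	0	-9
sample0024	sample0024	0	0	0	-9
sample0025	sample0025	0	0	0	-9
sample0026	sample0026	0	0	0	-9
sample0027	sample0027	0	0	0	-9
sample0028	sample0028	0	0	0	-9
sample0029	sample0029	0	0	0	-9
sample0030	sample0030	0	0	0	-9
sample0031	sample0031	0	0	0	-9
sample0032	sample0032	0	0	0	-9
sample0033	sample0033	0	0	0	-9
sample0034	sample0034	0	0	0	-9
sample0035	sample0035	0	0	0	-9
sample0036	sample0036	0	0	0	-9
sample0037	sample0037	0	0	0	-9
sample0038	sample0038	0	0	0	-9
sample0039	sample0039	0	0	0	-9
sample0040	sample0040	0	0	0	-9
sample0041	sample0041	0	0	0	-9
sample0042	sample0042	0	0	0	-9
sample0043	sample0043	0	0	0	-9
sample0044	sample0044	0	0	0	-9
sample0045	sample0045	0	0	0	-9
sample0046	sample0046	0	0	0	-9
sample0047	sample0047	0	0	0	-9
sample0048	sample0048	0	0	0	-9
sample0049	sample0049	0	0	0	-9
sample0050	sample0050	0	0	0	-9
sample0051	sample0051	0	0	0	-9
sample0052	sample0052	0	0	0	-9
sample0053	sample0053	0	0	0	-9
sample0054	sample0054	0	0	0	-9
sample0055	sample0055	0	0	0	-9
sample0056	sample0056	0	0	0	-9
sample0057	sample0057	0	0	0	-9
sample0058	sample0058	0	0	0	-9
sample0059	sample0059	0	0	0	-9
sample0060	sample0060	0	0	0	-9
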