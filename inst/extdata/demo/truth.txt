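snp = rs00001
probe_i = probe0001
probe_j = probe0002
model = dominant
rho1 = 0.8
rho2 = 0
rho_het = 0.8
maf = 0.3
n_samples = 60
seed = 20151019
m1 = 25
m2 = 35
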