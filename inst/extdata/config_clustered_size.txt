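# size of the clustered test vs the naive HSIC under the clustered null
design = clustered_null
m = 100
p = 100
rho_w = 0.5
rho_c = 0.5
statistics = hsic_new,hsic
methods = pearson3
n_replicates = 1000
alpha = 0.05
seed = 20260002
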