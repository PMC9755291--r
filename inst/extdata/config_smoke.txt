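# one-replicate smoke run
design = clustered_alternative
m = 20
p = 10
rho_w = 0.5
rho_c = 0.5
eta = 0.5
statistics = hsic_new,hsic_mean
methods = permutation
n_perms = 99
n_replicates = 1
seed = 1
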