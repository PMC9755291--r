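# empirical size of the plain HSIC under the i.i.d. Gaussian design
design = iid_normal
n = 50
p = 50
statistics = hsic
methods = pearson3
n_replicates = 1000
alpha = 0.05
seed = 20260001
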