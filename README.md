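# chsic — kernel independence tests for cluster-correlated data

`chsic` tests whether two multivariate variables are independent when the
samples are **cluster-correlated** — repeated clinic visits of the same
subject, family members, longitudinal series — so that samples are not
exchangeable but clusters are. The motivating use case is screening
microbiome composition against metabolic pathways measured across repeated
visits, but nothing in the package is specific to those data types.

## The statistics

The Hilbert–Schmidt independence criterion (HSIC) measures dependence of
arbitrary form through kernel matrices $K_X$, $K_Y$ on the $N$ samples:

$$\widehat{\mathrm{HSIC}} = \frac{\mathrm{tr}(\tilde K_X \tilde K_Y)}{N^2},
\qquad \tilde K = H_N K H_N,\; H_N = I - \tfrac{1}{N}\mathbf{11}^t .$$

Calibrated by sample permutations, this test is badly anticonservative under
cluster correlation (empirical size up to 1.0 at nominal 0.05 in the bundled
simulations). The clustered statistic collapses each kernel to an
$m \times m$ **cluster-wise kernel** — entry $(a,b)$ is the mean of the
kernel block between clusters $a$ and $b$ — and uses

$$\mathrm{HSIC}_{new} = \mathrm{tr}\!\left(\tilde K_X^{cl} \tilde K_Y^{cl}\right),$$

with permutations over the $m$ cluster indices, which are exchangeable under
the null. For large $m$, p-values come from a **Pearson type III**
(moment-matched shifted gamma) approximation using the *exact* closed-form
mean, variance and skewness of the permutation distribution, making single
tests fast enough for screens at Bonferroni-level thresholds.

Kernels: Gaussian with median-heuristic bandwidth,
$k(x,x') = \exp(-\lVert x-x'\rVert^2/h^2)$, and Bray–Curtis (Gower-centered,
PSD-truncated) for compositional data. See the methods vignette
(`vignettes/clustered-kernel-independence.Rmd`) for all conventions and
design choices.

## Worked example

```r
library(chsic)
set.seed(42)

# 50 clusters of 3 visits; half of Y's 20 outcomes depend on one X column
sim <- generate_clustered_alternative(m = 50, p = 20, eta = 0.5,
                                      rho_w = 0.5, rho_c = 0.7)
hsic_test(sim$x, sim$y, clusters = sim$clusters,
          method = "permutation", n_perms = 999, seed = 1)
```

```
	Clustered HSIC independence test

data:  sim$x and sim$y
hsic_new = 10.59, units = 50 clusters (N = 150), p-value = 0.024
method: permutation (999 permutations)
kernels: x = gaussian (bandwidth 5.429), y = gaussian (bandwidth 5.836)
```

The statistic is the trace of the product of the two centered cluster-wise
kernels; the p-value is the fraction of cluster permutations with a
statistic at least as large (with the +1 validity correction). The same
test with the analytic approximation reports the exact permutation moments
it matched:

```r
summary(hsic_test(sim$x, sim$y, clusters = sim$clusters, method = "pearson3"))
```

```
	Clustered HSIC independence test

data:  sim$x and sim$y
hsic_new = 10.59, units = 50 clusters (N = 150), p-value = 0.02936
method: Pearson type III moment approximation
kernels: x = gaussian (bandwidth 5.429), y = gaussian (bandwidth 5.836)

Exact permutation moments:
  mean 8.93339, variance 0.512684, skewness 1.15413
```

Both p-values agree at Monte-Carlo resolution; the approximation needs no
permutations at all. Group-wise screens (`hsic_screen`) run one test per
named group of Y columns with a Bonferroni threshold, and
`run_experiment()` tabulates size/power over the bundled synthetic designs.
A thin command-line wrapper lives at `inst/cli/chsic`
(`test` / `simulate` / `screen` subcommands; configs under `inst/extdata/`).

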