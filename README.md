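# laguerreGC

Conditional Granger causality with discrete-time Laguerre regressors,
plus the synthetic benchmarking harness used to validate it.

## The problem

Granger causality (GC) declares a directed influence $j \to i$ when the
past of channel $j$ improves the prediction of channel $i$ beyond what
$i$'s own past and all other channels already provide. The classical
estimator fits nested multivariate autoregressive (MVAR) models with
explicit lags $1 \dots p$; for densely recorded, long-memory signals
(e.g. band-limited power envelopes of neural sources) the required $p$
and the resulting $L \cdot p$ coefficients per target quickly outgrow
the data.

This package implements a parsimonious generalization: each channel is
convolved with the discrete-time orthonormal Laguerre functions

$$\phi_m(n) = \alpha^{(n-m)/2}(1-\alpha)^{1/2}\sum_{j=0}^{m}(-1)^j
\binom{n}{j}\binom{m}{j}\alpha^{m-j}(1-\alpha)^j, \quad 0 \le \alpha < 1,$$

yielding $p$ compact regressors per channel whose memory is controlled
by the single global decay parameter $\alpha$. Setting $\alpha = 0$
recovers classical MVAR-GC exactly. Per ordered pair the package
reports the GC strength $s_{j\to i} = \ln(\mathrm{RSS}_r /
\mathrm{RSS}_{ur})$, the F ratio $\frac{\mathrm{RSS}_r -
\mathrm{RSS}_{ur}}{\mathrm{RSS}_{ur}}\cdot\frac{N_{obs}-2m}{m}$
($m = p$) and its upper-tail p-value.

The harness provides: random binary directed ground-truth networks at
exact edge density; a coupled stochastic node simulator with
$1/f^\beta$ long-range-correlated noise, cubic damping and randomly
delayed (0–12 s) integral couplings; and ROC/AUC benchmarking of the
Laguerre estimator against the classical baseline under pooled-links
and per-network-median aggregations.

## Worked example

Simulate a 17-node network at density 0.0625 and score both estimators
against the ground truth:

```r
library(laguerreGC)

net <- randomNetwork(17, 0.0625, seed = 3)
net
#> DirectedNetwork: 17 nodes, 17 edges (density 0.0625)

sim <- simulateNetwork(net, simConfig(seed = 13))
sim
#> SimOutput: 17 channels x 10000 retained samples (h = 0.25 s)
#>   source delays (samples): 24 47 37 25 13 23 43 19 25 23 29 1 1 0 39 14 3

lgc  <- pairwiseConditionalGC(seriesMatrix(sim), p = 10, alpha = 0.595)
mvar <- mvarGC(seriesMatrix(sim), p = 10)
offd <- row(adjacency(net)) != col(adjacency(net))
c(lgc  = rocAuc(strengths(lgc)[offd],  adjacency(net)[offd]),
  mvar = rocAuc(strengths(mvar)[offd], adjacency(net)[offd]))
#>       lgc      mvar
#> 0.8996540 0.6110727
```

The Laguerre estimator ranks true edges well above the classical
baseline on the same series: with only 10 coefficients per channel it
captures couplings delayed by up to 12 s (48 samples), far beyond the
10-sample window the classical model can see. A full sweep
(`alphaDensitySweep`) maps the gain as a function of network density
and $\alpha$; the gain peaks for $\alpha$ around 0.6 and vanishes by
construction at $\alpha = 0$.

A thin command-line front-end over the same functions is installed at
`inst/cli/lgc.R` (`simulate`, `estimate`, `benchmark` subcommands; TSV
matrices channels x time, JSON manifests, exit codes 0/2/3).

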