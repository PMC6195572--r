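# markovcp

Multiscale Bayesian modelling of temporal contact networks: arbitrary-order
Markov chains of edge activations whose transition probabilities switch
abruptly at inferred change points, with surrogate generation, discrete-time
SIR/SIS epidemic simulation and waiting-time diagnostics.

## Who this is for

Researchers working with time-stamped contact data — wearable-sensor
proximity studies, hospital-ward contact tracing, any record of the form
`t u v` — who want to ask: *how much short-time memory do the edge dynamics
carry, where does the network's behaviour change abruptly, and do the
fitted dynamics reproduce spreading processes observed on the real data?*

## The model

The edge sequence $s = \{x_t\}$, $t = 1..E$, over $D$ distinct edges, is an
order-$n$ Markov chain within each of $M+1$ temporal segments, with a
separate transition matrix $p^l_{x,\mathbf{x}}$ per segment. Transition
probabilities are integrated out under uniform Dirichlet priors, giving the
closed-form joint marginal likelihood

$$P(x, l \mid n) = 2^{-D(M+1)}\frac{M!\,(E-M)!}{(E+1)!}
  \prod_l \prod_{\mathbf{x}} \frac{(D_l-1)!}{(k^l_{\mathbf{x}}+D_l-1)!}
  \prod_x a^l_{x,\mathbf{x}}!$$

which penalizes extra segments and extra memory automatically. The
segmentation is sampled by Metropolis–Hastings with split/merge/shift moves
(compiled hot loop, analytic Hastings ratios); the Markov order is selected
by comparing evidences; the change-point model is compared against the
stationary baseline by the posterior odds ratio
$\Lambda = P(x,l\mid n)/P(x,l_0\mid n_0)$.

## Worked example

Plant a ground-truth model (three regimes of an order-1 chain over 6 edges,
sharply distinct matrices), generate a sequence from it, and recover the
structure:

```r
library(markovcp)

pm  <- make_planted_model(D = 6, n = 1, segment_lengths = c(1500, 1500, 1500),
                          alpha = 0.1, seed = 1)
g   <- generate_planted(pm, seed = 2)
fit <- fit_changepoints(g$seq, order = 1, runs = 3, seed = 3)
fit
#> Markov chain with change points
#>   order n        : 1
#>   E, D           : 4500 , 6
#>   change points M: 2
#>   boundaries     : 1500, 3000
#>   log joint      : -1714.096
#>   q-hat = M/E    : 0.0004444444
```

Both planted boundaries are recovered exactly (the planted truth is
1500, 3000), and `q-hat = M/E` estimates the per-step change-point rate.
Against the forced single-segment (stationary) baseline:

```r
base <- fit_stationary_baseline(g$seq, order = 1)
posterior_odds_ratio(fit, base, log = TRUE)
#> [1] 2068.264
```

a log odds ratio of ≈ 2068 — overwhelming evidence for the nonstationary
model on these data. Surrogate sequences and epidemics then probe whether
the fit reproduces dynamics:

```r
sur   <- simulate(fit, nsim = 1, seed = 4)[[1]]    # surrogate edge sequence
curve <- ensemble_infected_curve(g$seq, "SIR", beta = 0.4, gamma = 0.01,
                                 realizations = 20, seed = 5)
head(curve, 3)
#>   t mean_X  stderr_X
#> 1 0   1.00 0.0000000
#> 2 1   1.05 0.0500000
#> 3 2   1.35 0.1312892
```

`mean_X` is the average number of infected nodes per step (one random seed
node per realization), `stderr_X` the standard deviation of the mean.
`waiting_times()` gives the pooled inter-event distribution of edges, the
other diagnostic used to compare data against surrogates
(`curve_discrepancy()` summarizes curve differences).

Real data enter through `read_temporal_edges("file.txt")` (whitespace
`t u v` records, `#` comments, extra columns ignored) followed by
`tokenize()`. A command-line wrapper with subcommands `fit-stationary`,
`fit-changepoints`, `compare`, `generate`, `epidemic`, `waiting-times` and
`synth` is in `inst/cli/markovcp` (see `?dispatch`).

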