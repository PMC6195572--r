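---
title: "Multiscale Markov models with change points for temporal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale Markov models with change points for temporal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r}
library(markovcp)
```

## The model

A temporal contact network — for example, face-to-face proximity data
collected by wearable sensors — is represented here as an ordered sequence of
edge activations. After flattening simultaneous records into consecutive
steps, the data are a sequence $s = \{x_t\}$, $t = 1,\dots,E$, over an
alphabet of $D$ distinct edges ("tokens"), each token standing for one
undirected node pair.

Two time scales matter for processes running on such networks. At short
times, the identity of the next active edge depends on the recent past: an
edge that just fired tends to fire again. At long times, the overall pattern
of activity shifts abruptly — class breaks, meal times, shift changes. The
package models both at once.

**Within a segment** the sequence is an order-$n$ Markov chain: the
probability of token $x_t$ depends on the memory
$\mathbf{x}_{t-1} = (x_{t-1},\dots,x_{t-n})$ through a transition matrix
$p_{x,\mathbf{x}}$, so that
$P(s \mid p, n) = \prod_{x,\mathbf{x}} p_{x,\mathbf{x}}^{a_{x,\mathbf{x}}}$,
with $a_{x,\mathbf{x}}$ the observed transition counts. **Across segments**
the transition matrix switches abruptly at $M$ unknown change points, each
segment $l$ carrying its own matrix $p^l$ and its own effective alphabet of
size $D_l$.

Maximum likelihood cannot choose $n$ or $M$: the likelihood grows
monotonically with both, so it always overfits. Instead the transition
probabilities are integrated out under uniform Dirichlet priors. For the
stationary model this yields the closed-form marginal likelihood

$$P(s \mid n) = \prod_{\mathbf{x}} \frac{(D-1)!}{(k_{\mathbf{x}}+D-1)!}
  \prod_x a_{x,\mathbf{x}}!,$$

with $k_{\mathbf{x}} = \sum_x a_{x,\mathbf{x}}$, and for the change-point
model the joint integrated likelihood

$$P(x, l \mid n) = 2^{-D(M+1)}\,\frac{M!\,(E-M)!}{(E+1)!}
  \prod_l \prod_{\mathbf{x}}
  \frac{(D_l-1)!}{(k^l_{\mathbf{x}}+D_l-1)!} \prod_x a^l_{x,\mathbf{x}}!,$$

where the $2^{-D}$ factor per segment is the prior for that segment's
alphabet (a uniformly chosen subset of the $D$ observed edges) and the
$M!(E-M)!/(E+1)!$ factor comes from integrating the per-step change-point
probability $q$ under a uniform prior. Both expressions are evaluated
entirely in log space via `lgamma`; no integer factorial appears anywhere.
These marginal likelihoods penalize complexity automatically: an extra
segment or an extra order of memory must earn its keep in predictive terms.

Model selection then works in two directions:

* **Order selection.** `order_posterior()` combines the per-order evidences
  with a flat prior over $n = 0,\dots,n_\max$ (default $n_\max = 3$) through
  a log-sum-exp normalization, so evidences hundreds of log-units apart are
  handled exactly.
* **Stationary vs nonstationary.** `posterior_odds_ratio()` compares the
  joint likelihood of the best segmentation against the forced
  single-segment baseline, $\Lambda = P(x, l \mid n)/P(x, l_0 \mid n_0)$;
  $\Lambda > 1$ favours the change-point model.

## Inferring the segmentation

The posterior over segmentations is explored by Metropolis-Hastings
(`fit_changepoints()`). Three moves are proposed with equal probability:

* **split** — pick one of the $M+1$ segments uniformly, cut it at a
  uniformly chosen internal position;
* **merge** — remove one of the $M$ boundaries uniformly;
* **shift** — move a uniformly chosen boundary to a uniform position
  strictly between its neighbours.

Split and merge are mutual inverses; the Hastings correction for a split of
a length-$L$ segment is $L-1$ (and its reciprocal for the merge), computed
analytically from the choice probabilities. Shift is symmetric. A drawn move
that cannot be applied (merge with $M = 0$, split of a length-one segment)
counts as a proposal and leaves the state unchanged, which keeps the kernel
well defined. Each chain starts from a single segment. The proposal engine
is implemented in compiled code with per-segment likelihood terms cached, so
a proposal costs only the re-evaluation of the affected segments; after
every run the best segmentation's likelihood is recomputed from scratch so
no floating-point drift can accumulate.

Three design choices deserve a note, since the formulation leaves them open:

* **Memory across boundaries.** The memory of the first transitions inside a
  segment is the actual preceding tokens of the global sequence — a change
  point switches which matrix generates a step, it does not reset the
  conditioning. This is the reading with no extra boundary term.
* **Initial-memory convention.** The order-$n$ likelihood conditions on the
  first $n$ tokens (transitions are counted for $t > n$). This keeps the
  marginal likelihood exactly normalized over continuations of a fixed
  prefix — a property the test suite verifies by enumeration. The caveat is
  that different orders condition on slightly different data;
  `order_posterior(..., shared_prefix = TRUE)` makes all orders condition on
  the same first $n_\max$ tokens when strict comparability matters.
* **Alphabet-prior scale.** The per-segment alphabet prior uses the global
  alphabet size $D$ (the factor $2^{-D}$ per segment), the literal reading
  of the prior above, while the Dirichlet factors inside a segment use the
  segment's observed alphabet $D_l$.

**Stopping and restarts.** A run stops when the best joint likelihood has
not improved for $200\,(M+1)$ consecutive proposals, with at least $10E$
proposals in total (and a hard cap of $200E$). The patience scales with $M$
because the number of distinct moves grows with the number of segments. The
default is 10 independent restarts, keeping the best; convergence on data of
the kind modelled here is fast and the restarts agree almost always, so the
examples and experiments below use 3–5 restarts. The Markov order is held
fixed within a chain and compared across chains afterwards
(`select_order()`): a joint order-move would settle almost immediately
anyway while costing $O(E)$ per proposal.

**Correctness checks built into the tests.** For short sequences
($E \le 14$) all $2^{E-1}$ segmentations can be enumerated exactly
(`exact_segmentation_posterior()`); the sampler's long-run visit frequencies
match that exact posterior within total variation 0.05, and its reported
maximum agrees with the enumeration argmax. Detailed balance is verified
identity-by-identity on random instances via the R-level `propose_move()` /
`mh_accept_prob()` pair.

## Surrogates, epidemics and waiting times

The fitted models are judged by what they generate, not only by their
likelihood. `simulate()` on a fit draws surrogate sequences: boundaries held
at their inferred positions, tokens drawn from the per-segment ML matrices,
memory carried across boundaries. The initial memory is drawn from the
empirical distribution of length-$n$ windows of the training sequence
(stationary-consistent and data-driven); a memory never observed in a
segment's training counts falls back to that segment's empirical token
marginal — surrogates can reach memories the data never visited, and the
marginal is the least-structured segment-local choice.

`simulate_epidemic()` runs discrete-time SIR/SIS dynamics on the event
clock: at step $t$ only the active edge can transmit (probability $\beta$ if
exactly one endpoint is infected), then every node infected at $t-1$
recovers with probability $\gamma$. A node infected at step $t$ cannot
recover at $t$; a node may transmit and recover in the same step. With
$\beta = 1, \gamma = 0$ the final infected set is exactly the
time-respecting reachability set of the seed, which the tests verify
against an independent forward-scan oracle. The seeding protocol is one
uniformly random initially infected node per realization (configurable);
`ensemble_infected_curve()` averages $X(t)$ over realizations and reports
the standard error of the mean, resampling both the surrogate sequence and
the dynamics when several surrogates are supplied.

`waiting_times()` collects, per edge, the gaps between consecutive
occurrences on the event clock, pooled across edges (log-binned, ten bins
per decade by default). For an i.i.d. order-0 sequence the pooled gaps
follow the geometric law implied by the token frequencies — a closed form
the tests check at $E = 10^5$ with a Kolmogorov–Smirnov distance below
0.02. Waiting times are measured on the event clock because that is the
model's notion of time; mapping back to raw timestamps is a presentation
choice left to the caller.

## The planted-model benchmark

`make_planted_model()` / `generate_planted()` provide ground truth without
any external data: per-segment transition matrices with rows drawn from a
symmetric Dirichlet($\alpha$) over $D$ tokens, a known order and known
boundaries, forward-simulated with memory carried across boundaries. The
concentration $\alpha$ is the single knob for how distinguishable the
regimes are: $\alpha = 0.1$ (the default) gives spiky, sharply distinct
rows; $\alpha \to \infty$ gives indistinguishable uniform rows.

What the generator emulates is exactly the generative process the inference
assumes — which is the point: it makes recovery experiments well-posed.
What it does **not** emulate are features of real proximity data that lie
outside the model class: daily periodicity, gradual (rather than abrupt)
drift, node-level community structure, and the appearance of brand-new
edges late in the recording. Passing the recovery experiments therefore
demonstrates the correctness of the inference machinery, not that real
contact data are Markov chains with change points.

```{r}
pm <- make_planted_model(D = 4, n = 0, segment_lengths = c(400, 400),
                         alpha = 0.1, seed = 7)
g <- generate_planted(pm, seed = 8)
fit <- fit_changepoints(g$seq, order = 0, runs = 3, seed = 9)
fit
boundary_recovery_error(g$segmentation, fit)
```

## Experiment scales and numerical conventions

The recovery experiments shipped with the package use, as their standard
conditions: four segments of length 2000 at $D = 10$, $\alpha = 0.1$,
order 0 for boundary recovery (success: $M$ recovered and every true
boundary within ±50 steps, in at least 9 of 10 seeded repetitions); and
$E = 2\times 10^4$, $D = 5$, three segments for order recovery between
$n = 0$ and $n = 1$. The enumeration cross-check runs at $E = 10$–$12$ with
$2\times 10^5$ proposals. These sizes are the package's chosen defaults for
its own validation experiments and are reproduced both in the test suite
and in `scripts/acceptance.R`.

Numerical conventions worth knowing:

* boundary $b$ means "the matrix changes between steps $b$ and $b+1$"
  (1-based steps);
* simultaneous records in an input edge list are flattened in stable file
  order — the tie rule is unspecified in the data convention itself, and
  stable order is the simplest deterministic choice;
* repeated identical consecutive records are kept: the data are proximity
  pings and repetition is informative for chains of order $n \ge 1$;
* every stochastic function takes an explicit `seed`; one master seed
  spawns per-run streams deterministically, and the caller's RNG state is
  always restored;
* `tokenize()` guarantees a dense alphabet (every token occurs); the
  low-level `token_sequence()` constructor accepts an explicit `D` with
  unobserved tokens so that planted sequences in which a rare token never
  fires remain representable.

## Limitations

The model is a single-edge-per-step, discrete-time description: contact
durations and the real-time axis are deliberately flattened onto the event
clock. Change points are abrupt by construction; slow drift will be
approximated by a staircase of segments. The segmentation reported is a
maximum a posteriori point estimate (with multi-restart search), not a
posterior average, and edges never observed in training can never appear in
surrogates. Order selection compares maximum joint likelihoods per order
rather than marginalizing over segmentations; for strongly periodic,
near-deterministic sequences the per-order prefix convention can tip the
evidence toward the largest order that fits, which is why the shared-prefix
option exists.
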