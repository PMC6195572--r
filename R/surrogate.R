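# Surrogate-sequence generation from fitted models.
#
# Both samplers share one core: within each segment tokens are drawn from
# that segment's fitted transition probabilities, the memory always carries
# across boundaries, and a memory never observed in training falls back to
# the segment's empirical token marginal.

# hashed lookup memory-key -> (successor tokens, probabilities); keys are
# prefixed with "m" because "" (the order-0 memory) is not a legal name
env_key <- function(key) paste0("m", key)

make_lookup <- function(mem, token, count) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  idx <- split(seq_along(count), mem)
  keys <- names(idx)
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    assign(env_key(keys[j]),
           list(tok = token[i], prob = count[i] / sum(count[i])),
           envir = env)
  }
  env
}

# empirical token marginal over steps lo..hi of the training sequence
token_marginal <- function(x, lo, hi) {
  tab <- table(x[lo:hi])
  list(tok = as.integer(names(tab)), prob = as.numeric(tab) / sum(tab))
}

draw_one <- function(d) d$tok[sample.int(length(d$tok), 1L, prob = d$prob)]

# core sampler; boundaries define segments of the *output* sequence
sample_tokens_core <- function(n, E, boundaries, lookups, marginals,
                               init_tokens) {
  x <- integer(E)
  if (n > 0L) x[seq_len(min(n, E))] <- init_tokens[seq_len(min(n, E))]
  lab <- findInterval(seq_len(E), boundaries + 0.5) + 1L  # segment of step t
  if (n == 0L) {
    lo <- c(1L, boundaries + 1L); hi <- c(boundaries, E)
    for (l in seq_along(lo)) {
      d <- get0(env_key(""), envir = lookups[[l]], inherits = FALSE) %||%
        marginals[[l]]
      x[lo[l]:hi[l]] <- d$tok[sample.int(length(d$tok), hi[l] - lo[l] + 1L,
                                         replace = TRUE, prob = d$prob)]
    }
  } else if (E > n) {
    for (t in (n + 1L):E) {
      key <- env_key(paste(x[t - seq_len(n)], collapse = ","))
      l <- lab[t]
      d <- get0(key, envir = lookups[[l]], inherits = FALSE) %||% marginals[[l]]
      x[t] <- draw_one(d)
    }
  }
  x
}

#' Sample a surrogate sequence from a stationary fit
#'
#' Draws the initial memory from the empirical distribution of length-`n`
#' windows of the training sequence, then samples each subsequent token from
#' the fitted transition probabilities; a memory absent from the training
#' counts falls back to the global empirical token distribution.
#'
#' @param model a [fit_markov()] object.
#' @param E length of the surrogate (defaults to the training length).
#' @param seed RNG seed.
#' @return a [token_sequence()] sharing the training alphabet.
#' @export
sample_stationary <- function(model, E = model$seq$E, seed = NULL) {
  stopifnot(inherits(model, "markov_fit"))
  n <- model$order
  cnt <- model$counts
  lookup <- make_lookup(cnt$mem, cnt$token, cnt$count)
  marg <- token_marginal(model$seq$tokens, 1L, model$seq$E)
  run_seeded(seed, {
    init <- if (n > 0L) {
      s <- sample.int(model$seq$E - n + 1L, 1L)
      model$seq$tokens[s:(s + n - 1L)]
    } else integer(0)
    x <- sample_tokens_core(n, E, integer(0), list(lookup), list(marg), init)
    token_sequence(x, D = model$seq$D, alphabet = model$seq$alphabet,
                   N = model$seq$N)
  })
}

#' Sample a surrogate sequence from a change-point fit
#'
#' Boundaries are held fixed at their inferred positions; inside segment `l`
#' tokens are drawn from that segment's maximum-likelihood transition
#' probabilities.  The memory carries across boundaries, and a memory unseen
#' within a segment's training counts falls back to the segment's empirical
#' token marginal.  The surrogate has the training length, so at `M = 0`
#' this is the stationary sampler.
#'
#' @param model a [fit_changepoints()] object.
#' @param seed RNG seed.
#' @return a [token_sequence()] sharing the training alphabet.
#' @export
sample_segmented <- function(model, seed = NULL) {
  stopifnot(inherits(model, "cpm_fit"))
  n <- model$order
  seq <- model$seq
  rng <- segment_ranges(model$segmentation)
  lookups <- lapply(model$counts$segments, function(s)
    make_lookup(s$mem, s$token, s$count))
  marginals <- lapply(seq_len(nrow(rng)), function(l)
    token_marginal(seq$tokens, rng[l, 1L], rng[l, 2L]))
  run_seeded(seed, {
    init <- if (n > 0L) {
      s <- sample.int(seq$E - n + 1L, 1L)
      seq$tokens[s:(s + n - 1L)]
    } else integer(0)
    x <- sample_tokens_core(n, seq$E, model$boundaries, lookups, marginals,
                            init)
    token_sequence(x, D = seq$D, alphabet = seq$alphabet, N = seq$N)
  })
}

#' Simulate surrogate sequences from a fitted stationary chain
#'
#' @param object a `markov_fit`.
#' @param nsim number of surrogate sequences.
#' @param seed master seed (per-replicate seeds are derived from it).
#' @param E surrogate length.
#' @param ... unused.
#' @return a list of `nsim` [token_sequence()] objects.
#' @export
simulate.markov_fit <- function(object, nsim = 1, seed = NULL,
                                E = object$seq$E, ...) {
  seeds <- run_seeded(seed, draw_run_seeds(nsim))
  lapply(seeds, function(s) sample_stationary(object, E = E, seed = s))
}

#' Simulate surrogate sequences from a fitted change-point model
#'
#' @param object a `cpm_fit`.
#' @param nsim number of surrogate sequences.
#' @param seed master seed.
#' @param ... unused.
#' @return a list of `nsim` [token_sequence()] objects.
#' @export
simulate.cpm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- run_seeded(seed, draw_run_seeds(nsim))
  lapply(seeds, function(s) sample_segmented(object, seed = s))
}
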