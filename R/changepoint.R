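#' Segmentation of a token sequence
#'
#' A segmentation is a strictly increasing set of `M` boundaries in
#' `1..E-1`; boundary `b` means the transition matrix changes between steps
#' `b` and `b + 1` (1-based), giving `M + 1` non-empty segments.
#'
#' @param boundaries integer vector of boundary positions (possibly empty).
#' @param E sequence length.
#' @return an object of class `segmentation` with fields `boundaries`, `M`,
#'   `E`.
#' @export
segmentation <- function(boundaries, E) {
  boundaries <- as.integer(sort(boundaries))
  E <- as.integer(E)
  if (length(boundaries)) {
    if (any(boundaries < 1L) || any(boundaries > E - 1L))
      stop("boundaries must lie in 1..E-1")
    if (anyDuplicated(boundaries)) stop("duplicate boundary")
  }
  structure(list(boundaries = boundaries, M = length(boundaries), E = E),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("Segmentation: E = ", x$E, ", M = ", x$M, " change point(s)",
      if (x$M) paste0(" at ", paste(x$boundaries, collapse = ", ")), "\n",
      sep = "")
  invisible(x)
}

# segment label (0-based) of each step 1..E
segment_labels <- function(seg) {
  findInterval(seq_len(seg$E), c(seg$boundaries + 0.5))
}

# (lo, hi) step ranges of all segments
segment_ranges <- function(seg) {
  lo <- c(1L, seg$boundaries + 1L)
  hi <- c(seg$boundaries, seg$E)
  cbind(lo = lo, hi = hi)
}

#' Per-segment transition counts
#'
#' Attributes the transition at step `t` (for `t > n`) to the segment
#' containing `t`.  The memory is always the actual previous `n` tokens of
#' the global sequence, even when they lie across a boundary — the
#' segmentation changes which matrix generates a step, not what the chain
#' conditions on.  `D_l` is the number of distinct tokens occurring at steps
#' inside segment `l`.
#'
#' @param seq a [token_sequence()].
#' @param seg a [segmentation()] with `seg$E == seq$E`.
#' @param n Markov order.
#' @return an object of class `segmented_counts`: per-segment
#'   `transition_counts`-style lists plus `D_l`, and the global `D`, `E`,
#'   `order`, `boundaries`.
#' @export
segment_counts <- function(seq, seg, n) {
  stopifnot(inherits(seq, "token_sequence"), inherits(seg, "segmentation"))
  if (seg$E != seq$E) stop("segmentation length does not match sequence")
  n <- as.integer(n)
  if (seq$E <= n) stop("sequence shorter than order")
  x <- seq$tokens
  rng <- segment_ranges(seg)
  segments <- lapply(seq_len(nrow(rng)), function(l) {
    lo <- rng[l, 1L]; hi <- rng[l, 2L]
    D_l <- length(unique(x[lo:hi]))
    ts <- max(lo, n + 1L)
    if (ts > hi) {
      return(list(mem = character(0), token = integer(0), count = integer(0),
                  k = stats::setNames(numeric(0), character(0)), D_l = D_l))
    }
    t <- seq.int(ts, hi)
    mem <- memory_keys(x, n, t)
    key <- paste(mem, x[t], sep = "|")
    first <- !duplicated(key)
    count <- tabulate(match(key, key[first]), nbins = sum(first))
    k <- vapply(split(count, mem[first]), sum, 0)
    list(mem = mem[first], token = x[t][first], count = count, k = k, D_l = D_l)
  })
  structure(list(order = n, D = seq$D, E = seq$E,
                 boundaries = seg$boundaries, segments = segments),
            class = "segmented_counts")
}

#' Integrated joint likelihood of sequence and segmentation
#'
#' The joint probability of the token sequence and the segment labels with
#' the per-segment transition matrices, the change-point rate `q` and the
#' per-segment alphabets integrated out under uniform priors:
#' \deqn{P(x, l \mid n) = 2^{-D(M+1)} \frac{M!\,(E-M)!}{(E+1)!}
#'   \prod_l \prod_{\mathbf{x}} \frac{(D_l-1)!}{(k^l_{\mathbf{x}}+D_l-1)!}
#'   \prod_x a^l_{x,\mathbf{x}}!}{}
#' evaluated in log space.  At `M = 0` (and all tokens observed) this reduces
#' to the stationary evidence minus `D log 2 + log(E+1)`.
#'
#' @param sc a [segment_counts()] object.
#' @param seg the matching [segmentation()].
#' @return log joint likelihood (a scalar).
#' @export
log_joint_likelihood <- function(sc, seg) {
  stopifnot(inherits(sc, "segmented_counts"), inherits(seg, "segmentation"))
  if (!identical(sc$boundaries, seg$boundaries) || sc$E != seg$E)
    stop("segmented counts and segmentation do not match")
  M <- seg$M; E <- seg$E
  res <- -sc$D * (M + 1) * log(2) +
    lgamma(M + 1) + lgamma(E - M + 1) - lgamma(E + 2)
  for (s in sc$segments) {
    if (length(s$count)) {
      res <- res + sum(lgamma(s$D_l) - lgamma(s$k + s$D_l)) +
        sum(lgamma(s$count + 1))
    }
  }
  res
}

#' Propose a segmentation move
#'
#' One of three moves is drawn with equal probability: *split* (pick one of
#' the `M + 1` segments uniformly, split it at a uniformly chosen internal
#' position), *merge* (remove one of the `M` boundaries uniformly, merging
#' its two adjacent segments), or *shift* (move a uniformly chosen boundary
#' to a uniform position strictly between its neighbouring boundaries).
#' Split and merge are mutual inverses and the returned log Hastings ratio
#' `log P(l|l') - log P(l'|l)` accounts for that; shift is symmetric.  A draw
#' that cannot be applied (merge or shift with `M = 0`, split of a length-1
#' segment) returns the unchanged segmentation flagged `rejected`.
#'
#' Uses the current R random number stream.
#'
#' @param seg a [segmentation()].
#' @return a list with `seg` (the proposal), `log_ratio`, `move` (one of
#'   `"split"`, `"merge"`, `"shift"`) and `rejected` (logical).
#' @export
propose_move <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  M <- seg$M; E <- seg$E; b <- seg$boundaries
  move <- c("split", "merge", "shift")[sample.int(3L, 1L)]
  reject <- function() list(seg = seg, log_ratio = NA_real_, move = move,
                            rejected = TRUE)
  if (move == "split") {
    j <- sample.int(M + 1L, 1L)
    lo <- if (j == 1L) 1L else b[j - 1L] + 1L
    hi <- if (j == M + 1L) E else b[j]
    len <- hi - lo + 1L
    if (len < 2L) return(reject())
    cut <- lo + sample.int(len - 1L, 1L) - 1L      # in lo..hi-1
    new <- segmentation(c(b, cut), E)
    # forward: (1/3) * 1/(M+1) * 1/(len-1); reverse merge: (1/3) * 1/(M+1)
    list(seg = new, log_ratio = log(len - 1), move = move, rejected = FALSE)
  } else if (move == "merge") {
    if (M == 0L) return(reject())
    j <- sample.int(M, 1L)
    lo <- if (j == 1L) 1L else b[j - 1L] + 1L
    hi <- if (j == M) E else b[j + 1L]
    new <- segmentation(b[-j], E)
    list(seg = new, log_ratio = -log(hi - lo), move = move, rejected = FALSE)
  } else {
    if (M == 0L) return(reject())
    j <- sample.int(M, 1L)
    lo <- if (j == 1L) 0L else b[j - 1L]
    hi <- if (j == M) E else b[j + 1L]
    pos <- lo + sample.int(hi - lo - 1L, 1L)       # in lo+1..hi-1
    b2 <- b; b2[j] <- pos
    list(seg = segmentation(b2, E), log_ratio = 0, move = move,
         rejected = FALSE)
  }
}

#' Metropolis-Hastings acceptance probability
#'
#' `min(1, exp(log_post_new - log_post_old + log_proposal_ratio))`, where the
#' proposal ratio is `log P(l|l') - log P(l'|l)`.
#'
#' @param log_post_new,log_post_old log posterior (joint likelihood) of the
#'   proposed and current segmentations.
#' @param log_proposal_ratio log Hastings correction.
#' @return acceptance probability in `[0, 1]`.
#' @export
mh_accept_prob <- function(log_post_new, log_post_old, log_proposal_ratio) {
  stopifnot(is.finite(log_post_new), is.finite(log_post_old),
            is.finite(log_proposal_ratio))
  min(1, exp(log_post_new - log_post_old + log_proposal_ratio))
}

# Build the integer transition encoding consumed by the C++ sampler:
# 0-based memory ids and (memory, token) pair ids for steps t > n.
prep_transitions <- function(seq, n) {
  x <- seq$tokens; E <- seq$E
  t <- seq.int(n + 1L, E)
  mem <- memory_keys(x, n, t)
  mem_first <- !duplicated(mem)
  memid <- match(mem, mem[mem_first]) - 1L
  pair <- paste(mem, x[t], sep = "|")
  pair_first <- !duplicated(pair)
  pairid <- match(pair, pair[pair_first]) - 1L
  trans_mem <- rep(-1L, E); trans_mem[t] <- memid
  trans_pair <- rep(-1L, E); trans_pair[t] <- pairid
  list(trans_mem = trans_mem, trans_pair = trans_pair,
       U = sum(mem_first), P = sum(pair_first))
}

#' Infer change points by Metropolis-Hastings sampling
#'
#' Runs several independent Markov chains over segmentations, each starting
#' from a single segment (`M = 0`), proposing split/merge/shift moves
#' ([propose_move()] semantics, implemented in compiled code with cached
#' per-segment likelihood terms) and accepting them by the
#' Metropolis-Hastings criterion.  A run stops once no improvement of the
#' best joint likelihood has been seen for `patience * (M + 1)` consecutive
#' proposals, with at least `min_proposals` proposals in total.  The
#' highest-likelihood segmentation across runs is returned with its counts
#' and per-segment maximum-likelihood transition matrices.
#'
#' @param seq a [token_sequence()].
#' @param order Markov order `n` (held fixed during the run; use
#'   [select_order()] to compare orders).
#' @param runs number of independent restarts (default 10).
#' @param seed master seed; per-run streams are derived from it.
#' @param patience improvement patience multiplier (default 200).
#' @param min_proposals minimum proposals per run (default `10 * E`).
#' @param max_proposals hard cap per run (default `200 * E`).
#' @return an object of class `cpm_fit` with components `order`,
#'   `segmentation`, `boundaries`, `M`, `counts` (a [segment_counts()]
#'   object), `p` (list of per-segment MLE matrices), `log_joint`, `q_hat`,
#'   `log_joint_runs`, `proposals` and the training sequence `seq`.
#' @examples
#' pm <- make_planted_model(D = 4, n = 0, segment_lengths = c(300, 300),
#'                          alpha = 0.1, seed = 7)
#' g <- generate_planted(pm, seed = 8)
#' fit <- fit_changepoints(g$seq, order = 0, runs = 3, seed = 9)
#' fit
#' @export
fit_changepoints <- function(seq, order = 0L, runs = 10L, seed = NULL,
                             patience = 200, min_proposals = 10 * seq$E,
                             max_proposals = 200 * seq$E) {
  stopifnot(inherits(seq, "token_sequence"))
  order <- as.integer(order)
  if (seq$E <= order) stop("sequence shorter than order")
  pr <- prep_transitions(seq, order)
  results <- run_seeded(seed, {
    run_seeds <- draw_run_seeds(runs)
    lapply(run_seeds, function(s) {
      set.seed(s)
      cpm_mcmc_run(seq$tokens, pr$trans_mem, pr$trans_pair,
                   order, seq$D, pr$U, pr$P,
                   patience, min_proposals, max_proposals,
                   FALSE, 0)
    })
  })
  lj <- vapply(results, `[[`, 0, "log_joint")
  best <- results[[which.max(lj)]]
  seg <- segmentation(best$boundaries, seq$E)
  sc <- segment_counts(seq, seg, order)
  log_joint <- log_joint_likelihood(sc, seg)
  if (abs(log_joint - best$log_joint) > 1e-6)
    stop("internal error: sampler and recomputed log joint disagree")
  p <- lapply(sc$segments, function(s) {
    prob <- if (length(s$count)) s$count / unname(s$k[match(s$mem, names(s$k))]) else numeric(0)
    pp <- split(stats::setNames(prob, s$token), s$mem)
    structure(list(order = order,
                   p = lapply(pp, function(v) v[order(as.integer(names(v)))]),
                   D = seq$D),
              class = "transition_matrix")
  })
  structure(list(order = order, segmentation = seg,
                 boundaries = seg$boundaries, M = seg$M,
                 counts = sc, p = p, log_joint = log_joint,
                 q_hat = seg$M / seq$E,
                 log_joint_runs = lj,
                 proposals = vapply(results, `[[`, 0, "proposals"),
                 runs = runs, seed = seed, seq = seq, call = match.call()),
            class = "cpm_fit")
}

#' @rdname fit_changepoints
#' @export
infer_segmentation <- fit_changepoints

#' @export
print.cpm_fit <- function(x, ...) {
  cat("Markov chain with change points\n")
  cat("  order n        :", x$order, "\n")
  cat("  E, D           :", x$seq$E, ",", x$seq$D, "\n")
  cat("  change points M:", x$M, "\n")
  if (x$M) cat("  boundaries     :", paste(x$boundaries, collapse = ", "), "\n")
  cat("  log joint      :", format(x$log_joint), "\n")
  cat("  q-hat = M/E    :", format(x$q_hat), "\n")
  invisible(x)
}

#' @export
summary.cpm_fit <- function(object, ...) {
  print(object)
  len <- diff(c(0L, object$boundaries, object$seq$E))
  cat("  segment lengths:", paste(len, collapse = ", "), "\n")
  cat("  per-segment alphabet sizes:",
      paste(vapply(object$counts$segments, `[[`, 0L, "D_l"), collapse = ", "),
      "\n")
  cat("  log joint across runs:",
      paste(format(object$log_joint_runs, digits = 8), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.cpm_fit <- function(object, ...) object$p

#' @export
logLik.cpm_fit <- function(object, ...) {
  structure(object$log_joint, df = NA_integer_, nobs = object$seq$E - object$order,
            class = "logLik")
}

#' @export
plot.cpm_fit <- function(x, ...) {
  cum <- cumsum(!duplicated(x$seq$tokens))
  graphics::plot(seq_len(x$seq$E), cum, type = "l",
                 xlab = "step t (event clock)",
                 ylab = "distinct edges seen",
                 main = sprintf("Inferred change points (M = %d, n = %d)",
                                x$M, x$order), ...)
  if (x$M) graphics::abline(v = x$boundaries, lty = 2, col = "red3")
  invisible(x)
}

#' Exact posterior over all segmentations (enumeration oracle)
#'
#' Enumerates all `2^(E-1)` segmentations of a short sequence, evaluating the
#' joint integrated likelihood of each, and normalizes.  Only feasible for
#' `E <= 14`; intended as an exact reference for the MH sampler.
#'
#' @param seq a [token_sequence()] with `E <= 14`.
#' @param n Markov order.
#' @return a `data.frame` with columns `mask` (bit `b - 1` set if `b` is a
#'   boundary), `boundaries` (comma-separated string), `M`, `log_joint` and
#'   `prob`; probabilities sum to 1.
#' @export
exact_segmentation_posterior <- function(seq, n) {
  stopifnot(inherits(seq, "token_sequence"))
  if (seq$E > 14L) stop("enumeration infeasible for E > 14")
  E <- seq$E
  masks <- 0:(2^(E - 1L) - 1L)
  lj <- numeric(length(masks))
  bstr <- character(length(masks))
  M <- integer(length(masks))
  for (i in seq_along(masks)) {
    b <- which(bitwAnd(masks[i], bitwShiftL(1L, 0:(E - 2L))) != 0L)
    seg <- segmentation(b, E)
    lj[i] <- log_joint_likelihood(segment_counts(seq, seg, n), seg)
    bstr[i] <- paste(b, collapse = ",")
    M[i] <- length(b)
  }
  prob <- exp(lj - logsumexp(lj))
  data.frame(mask = masks, boundaries = bstr, M = M, log_joint = lj,
             prob = prob, stringsAsFactors = FALSE)
}

#' MH visit frequencies over segmentations
#'
#' Runs the sampler for a fixed number of proposals on a short sequence and
#' tallies how often each segmentation (encoded as a boundary bitmask) is the
#' current state.  For a correct sampler these frequencies converge to
#' [exact_segmentation_posterior()].
#'
#' @param seq a [token_sequence()] with `E <= 21`.
#' @param n Markov order.
#' @param proposals number of MH proposals.
#' @param seed RNG seed.
#' @return numeric vector of length `2^(E-1)`: relative visit frequency of
#'   each boundary bitmask (index `mask + 1`).
#' @export
mh_visit_frequencies <- function(seq, n, proposals, seed = NULL) {
  stopifnot(inherits(seq, "token_sequence"))
  if (seq$E > 21L) stop("histogram recording requires E <= 21")
  pr <- prep_transitions(seq, n)
  res <- run_seeded(seed,
    cpm_mcmc_run(seq$tokens, pr$trans_mem, pr$trans_pair,
                 as.integer(n), seq$D, pr$U, pr$P,
                 200, proposals, proposals, TRUE, proposals))
  res$hist / sum(res$hist)
}

#' Compare Markov orders under the change-point model
#'
#' Runs [fit_changepoints()] independently for each candidate order (the
#' order is kept fixed within each MCMC, since it settles almost immediately
#' when sampled jointly and is cheaper to compare afterwards) and reports the
#' order with the largest maximum joint likelihood.
#'
#' @param seq a [token_sequence()].
#' @param orders integer vector of candidate orders.
#' @param runs,seed,... passed to [fit_changepoints()]; per-order seeds are
#'   derived from `seed`.
#' @return a list with `fits` (named by order), `log_joint` (named vector)
#'   and `best` (the selected order).
#' @export
select_order <- function(seq, orders, runs = 10L, seed = NULL, ...) {
  orders <- as.integer(orders)
  fit_seeds <- run_seeded(seed, draw_run_seeds(length(orders)))
  fits <- lapply(seq_along(orders), function(i)
    fit_changepoints(seq, order = orders[i], runs = runs,
                     seed = fit_seeds[i], ...))
  names(fits) <- orders
  lj <- vapply(fits, `[[`, 0, "log_joint")
  list(fits = fits, log_joint = lj, best = orders[which.max(lj)])
}

#' Posterior odds ratio between two fitted change-point models
#'
#' `Lambda = exp(log_joint_a - log_joint_b)`.  With `b` the forced
#' single-segment fit (`M = 0`, the stationary baseline), `Lambda > 1` means
#' the data favour the nonstationary model.
#'
#' @param model_a,model_b `cpm_fit` objects fitted on the same sequence.
#' @param log return the log odds ratio instead.
#' @return the odds ratio (or its log).
#' @export
posterior_odds_ratio <- function(model_a, model_b, log = FALSE) {
  stopifnot(inherits(model_a, "cpm_fit"), inherits(model_b, "cpm_fit"))
  if (model_a$seq$E != model_b$seq$E)
    stop("models were fitted on sequences of different lengths")
  ll <- model_a$log_joint - model_b$log_joint
  if (log) ll else exp(ll)
}

#' Fit the forced single-segment (stationary) baseline
#'
#' Convenience wrapper producing the `M = 0` `cpm_fit` used as the baseline
#' of [posterior_odds_ratio()].
#'
#' @param seq a [token_sequence()].
#' @param order Markov order.
#' @return a `cpm_fit` with `M = 0`.
#' @export
fit_stationary_baseline <- function(seq, order = 0L) {
  order <- as.integer(order)
  seg <- segmentation(integer(0), seq$E)
  sc <- segment_counts(seq, seg, order)
  lj <- log_joint_likelihood(sc, seg)
  p <- mle_transitions(count_transitions(seq, order))
  structure(list(order = order, segmentation = seg, boundaries = integer(0),
                 M = 0L, counts = sc, p = list(p), log_joint = lj,
                 q_hat = 0, log_joint_runs = lj, proposals = 0L,
                 runs = 0L, seed = NULL, seq = seq, call = match.call()),
            class = "cpm_fit")
}

#' Maximum-likelihood change-point rate
#'
#' `q-hat = M / E`: the ML estimate of the per-step probability of inserting
#' a change point.
#'
#' @param seg a [segmentation()] or a `cpm_fit`.
#' @return a probability.
#' @export
estimate_q <- function(seg) {
  if (inherits(seg, "cpm_fit")) seg <- seg$segmentation
  stopifnot(inherits(seg, "segmentation"))
  seg$M / seg$E
}
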