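#' Transition counts of an order-n Markov chain
#'
#' Counts, for each observed memory (the `n` most recent tokens, most recent
#' first) and each following token, the number of transitions in the
#' sequence.  Transitions are counted for steps `t = t_start .. E` (1-based);
#' by default `t_start = n + 1`, i.e. the chain conditions on the first `n`
#' tokens.  Memories never observed are simply absent.
#'
#' @param seq a [token_sequence()].
#' @param n Markov order (`n = 0` counts plain token occurrences).
#' @param t_start first step whose transition is counted; must be `> n`.
#'   Setting `t_start = n_max + 1` for several orders makes their likelihoods
#'   condition on the same data (see [order_posterior()]).
#' @return an object of class `transition_counts` with parallel vectors
#'   `mem` (memory key, `""` for `n = 0`), `token`, `count`, the per-memory
#'   totals `k` (named by memory key), and `order`, `D`, `E`.
#' @export
count_transitions <- function(seq, n, t_start = n + 1L) {
  stopifnot(inherits(seq, "token_sequence"))
  n <- as.integer(n)
  if (n < 0L) stop("order must be non-negative")
  if (seq$E <= n) stop("sequence shorter than order")
  t_start <- max(as.integer(t_start), n + 1L)
  if (t_start > seq$E) stop("no transitions left after position ", t_start - 1L)
  x <- seq$tokens
  t <- seq.int(t_start, seq$E)
  mem <- memory_keys(x, n, t)
  tok <- x[t]
  key <- paste(mem, tok, sep = "|")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  count <- tabulate(idx, nbins = sum(first))
  mem_u <- mem[first]
  k <- vapply(split(count, mem_u), sum, 0)
  structure(list(order = n, mem = mem_u, token = tok[first], count = count,
                 k = k, n_transitions = length(t), D = seq$D, E = seq$E),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition counts: order ", x$order, ", ", length(x$k),
      " memory(ies), ", x$n_transitions, " transitions\n", sep = "")
  invisible(x)
}

#' Maximum-likelihood transition probabilities
#'
#' The ML estimate of the transition probability from memory `m` to token `x`
#' is the observed count divided by the number of transitions leaving `m`.
#'
#' @param counts a `transition_counts` object.
#' @return an object of class `transition_matrix`: a list `p` mapping each
#'   memory key to a named probability vector over the tokens observed after
#'   it, plus `order` and `D`.
#' @export
mle_transitions <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  # match() rather than name indexing: the order-0 memory key is ""
  prob <- counts$count / unname(counts$k[match(counts$mem, names(counts$k))])
  p <- split(stats::setNames(prob, counts$token), counts$mem)
  p <- lapply(p, function(v) v[order(as.integer(names(v)))])
  structure(list(order = counts$order, p = p, D = counts$D),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix: order ", x$order, ", ", length(x$p),
      " memory(ies)\n", sep = "")
  invisible(x)
}

#' Log marginal likelihood of a stationary order-n chain
#'
#' The probability of the observed transitions with the transition matrix
#' integrated out under a uniform Dirichlet prior on every row:
#' \deqn{P(s \mid n) = \prod_{\mathbf{x}} \frac{(D-1)!}{(k_{\mathbf{x}}+D-1)!}
#'   \prod_x a_{x,\mathbf{x}}!}{}
#' computed entirely in log space via `lgamma`.  Memories with no outgoing
#' transitions contribute a factor 1; an empty count set returns 0 (log of
#' probability 1).
#'
#' @param counts a `transition_counts` object.
#' @param D alphabet size (defaults to the full alphabet of the sequence the
#'   counts came from).
#' @return the log marginal likelihood (a scalar).
#' @export
log_marginal_stationary <- function(counts, D = counts$D) {
  stopifnot(inherits(counts, "transition_counts"))
  if (length(counts$count) == 0L) return(0)
  sum(lgamma(D) - lgamma(counts$k + D)) + sum(lgamma(counts$count + 1))
}

#' Posterior distribution over the Markov order
#'
#' Computes the marginal likelihood of each order `n = 0..n_max` and combines
#' them with a flat prior `1/(n_max+1)` via a log-sum-exp normalization, so
#' that evidences differing by hundreds of log units remain representable.
#' By default each order conditions on its own first `n` tokens; with
#' `shared_prefix = TRUE` all orders condition on the first `n_max` tokens,
#' making the likelihoods strictly comparable on identical data.
#'
#' @param seq a [token_sequence()].
#' @param n_max largest order considered (default 3).
#' @param shared_prefix condition all orders on the same length-`n_max`
#'   prefix.
#' @return an object of class `order_posterior` with named vectors
#'   `log_evidence` and `posterior` (over `"0".."n_max"`), and the modal
#'   order `mode`.
#' @export
order_posterior <- function(seq, n_max = 3L, shared_prefix = FALSE) {
  stopifnot(inherits(seq, "token_sequence"))
  n_max <- as.integer(n_max)
  if (n_max >= seq$E) stop("n_max must be smaller than the sequence length")
  orders <- 0:n_max
  log_ev <- vapply(orders, function(n) {
    ts <- if (shared_prefix) n_max + 1L else n + 1L
    log_marginal_stationary(count_transitions(seq, n, t_start = ts), seq$D)
  }, 0)
  names(log_ev) <- orders
  lp <- log_ev - logsumexp(log_ev)   # flat prior cancels
  structure(list(n_max = n_max, log_evidence = log_ev,
                 posterior = exp(lp),
                 mode = orders[which.max(log_ev)],
                 shared_prefix = shared_prefix),
            class = "order_posterior")
}

#' @export
print.order_posterior <- function(x, digits = 4, ...) {
  cat("Markov order posterior (flat prior on 0..", x$n_max, "):\n", sep = "")
  print(round(x$posterior, digits))
  cat("mode: n =", x$mode, "\n")
  invisible(x)
}

#' Fit a stationary Markov chain to a token sequence
#'
#' Counts transitions at the requested order (or at the posterior-modal order
#' when `order = NULL`), computes maximum-likelihood transition probabilities
#' and the Dirichlet-multinomial log evidence.
#'
#' @param seq a [token_sequence()].
#' @param order Markov order; `NULL` selects the order maximizing the
#'   marginal likelihood over `0..n_max`.
#' @param n_max order grid bound used when `order = NULL`.
#' @param shared_prefix passed to [order_posterior()].
#' @return an object of class `markov_fit` with components `order`, `counts`,
#'   `p` (the [mle_transitions()] matrix), `log_evidence`, `order_posterior`
#'   (when the order was selected) and the training sequence `seq`.
#' @seealso [simulate.markov_fit()], [fit_changepoints()]
#' @examples
#' s <- token_sequence(c(0, 1, 0, 1, 0, 1, 0, 0, 1, 0))
#' fit <- fit_markov(s, n_max = 2)
#' fit
#' coef(fit)
#' @export
fit_markov <- function(seq, order = NULL, n_max = 3L, shared_prefix = FALSE) {
  stopifnot(inherits(seq, "token_sequence"))
  op <- NULL
  if (is.null(order)) {
    op <- order_posterior(seq, n_max = n_max, shared_prefix = shared_prefix)
    order <- op$mode
  }
  counts <- count_transitions(seq, order)
  structure(list(order = as.integer(order), counts = counts,
                 p = mle_transitions(counts),
                 log_evidence = log_marginal_stationary(counts, seq$D),
                 order_posterior = op, seq = seq, call = match.call()),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("Stationary Markov chain fit\n")
  cat("  order n      :", x$order,
      if (!is.null(x$order_posterior)) "(selected by marginal likelihood)" else "",
      "\n")
  cat("  E, D         :", x$seq$E, ",", x$seq$D, "\n")
  cat("  log evidence :", format(x$log_evidence), "\n")
  invisible(x)
}

#' @export
summary.markov_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$order_posterior)) print(object$order_posterior)
  cat("  memories observed:", length(object$counts$k), "\n")
  invisible(object)
}

#' @export
coef.markov_fit <- function(object, ...) object$p

#' @export
logLik.markov_fit <- function(object, ...) {
  structure(object$log_evidence, df = NA_integer_,
            nobs = object$counts$n_transitions, class = "logLik")
}
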