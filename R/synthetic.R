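#' Planted change-point Markov model
#'
#' Builds a known ground-truth model for recovery experiments: one order-`n`
#' transition matrix per segment, each row drawn independently from a
#' symmetric Dirichlet with concentration `alpha` over the `D` tokens.
#' Small `alpha` (default 0.1) gives spiky, sharply distinguishable rows;
#' large `alpha` approaches uniform rows.
#'
#' @param D alphabet size (at least 2).
#' @param n Markov order.
#' @param segment_lengths integer vector of segment lengths (all `>= 1`);
#'   its cumulative sums (except the last) are the planted boundaries.
#' @param alpha Dirichlet concentration (`> 0`).
#' @param seed RNG seed.
#' @return an object of class `planted_model` with `matrices` (one
#'   `D^n x D` row-stochastic matrix per segment, rows indexed by memory key
#'   most-recent-first), `boundaries`, `E`, `D`, `order`, `alpha`.
#' @export
make_planted_model <- function(D, n, segment_lengths, alpha = 0.1,
                               seed = NULL) {
  D <- as.integer(D); n <- as.integer(n)
  segment_lengths <- as.integer(segment_lengths)
  if (D < 2L) stop("D must be at least 2")
  if (n < 0L) stop("order must be non-negative")
  if (length(segment_lengths) == 0L || any(segment_lengths < 1L))
    stop("segment lengths must all be >= 1")
  if (alpha <= 0) stop("alpha must be positive")
  n_mem <- D^n
  keys <- memory_key_grid(D, n)
  matrices <- run_seeded(seed, lapply(seq_along(segment_lengths), function(l) {
    m <- matrix(stats::rgamma(n_mem * D, shape = alpha), n_mem, D)
    m <- m / rowSums(m)
    dimnames(m) <- list(keys, as.character(0:(D - 1L)))
    m
  }))
  E <- sum(segment_lengths)
  structure(list(D = D, order = n, segment_lengths = segment_lengths,
                 boundaries = utils::head(cumsum(segment_lengths), -1L),
                 E = E, alpha = alpha, matrices = matrices, seed = seed),
            class = "planted_model")
}

# all memory keys of an order-n chain over tokens 0..D-1, most recent first,
# in row order matching encode_memory()
memory_key_grid <- function(D, n) {
  if (n == 0L) return("")
  g <- expand.grid(rep(list(0:(D - 1L)), n))  # column 1 = most recent
  do.call(paste, c(g, list(sep = ",")))
}

# 1-based row index of memory (x[t-1], ..., x[t-n])
encode_memory <- function(x_prev, D) {
  sum(x_prev * D^(seq_along(x_prev) - 1L)) + 1L
}

#' @export
print.planted_model <- function(x, ...) {
  cat("Planted model: D = ", x$D, ", order = ", x$order, ", ",
      length(x$segment_lengths), " segment(s), E = ", x$E,
      ", alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Generate a sequence from a planted model
#'
#' Forward-simulates the planted chain: the first `n` tokens are uniform,
#' each later token is drawn from the current segment's matrix given the
#' actual previous `n` tokens (memory carries across boundaries).
#'
#' @param model a [make_planted_model()] object.
#' @param seed RNG seed.
#' @return a list with `seq` (a [token_sequence()] with `D = model$D` and a
#'   synthetic alphabet) and `segmentation` (the planted ground truth).
#' @export
generate_planted <- function(model, seed = NULL) {
  stopifnot(inherits(model, "planted_model"))
  D <- model$D; n <- model$order; E <- model$E
  lab <- findInterval(seq_len(E), model$boundaries + 0.5) + 1L
  x <- run_seeded(seed, {
    x <- integer(E)
    if (n > 0L) x[seq_len(n)] <- sample.int(D, n, replace = TRUE) - 1L
    if (n == 0L) {
      lo <- c(1L, model$boundaries + 1L)
      hi <- c(model$boundaries, E)
      for (l in seq_along(lo)) {
        x[lo[l]:hi[l]] <- sample.int(D, hi[l] - lo[l] + 1L, replace = TRUE,
                                     prob = model$matrices[[l]][1L, ]) - 1L
      }
    } else {
      for (t in (n + 1L):E) {
        row <- encode_memory(x[t - seq_len(n)], D)
        x[t] <- sample.int(D, 1L, prob = model$matrices[[lab[t]]][row, ]) - 1L
      }
    }
    x
  })
  list(seq = token_sequence(x, D = D),
       segmentation = segmentation(model$boundaries, E),
       model = model)
}

#' Boundary recovery error
#'
#' For each true boundary, the distance to the nearest inferred boundary
#' (sequence ends count as trivial boundaries at 0 and `E` when nothing was
#' inferred), plus the difference in the number of change points.
#'
#' @param truth,inferred [segmentation()] objects (or `cpm_fit`s) on
#'   sequences of the same length.
#' @return a list with `distances` (one per true boundary), `max_distance`
#'   (0 when truth has no boundaries) and `delta_M`.
#' @export
boundary_recovery_error <- function(truth, inferred) {
  if (inherits(truth, "cpm_fit")) truth <- truth$segmentation
  if (inherits(inferred, "cpm_fit")) inferred <- inferred$segmentation
  stopifnot(inherits(truth, "segmentation"), inherits(inferred, "segmentation"))
  if (truth$E != inferred$E) stop("segmentations have different lengths")
  ref <- if (inferred$M) inferred$boundaries else c(0L, truth$E)
  d <- vapply(truth$boundaries, function(b) min(abs(b - ref)), 0)
  list(distances = d,
       max_distance = if (length(d)) max(d) else 0,
       delta_M = abs(truth$M - inferred$M))
}
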