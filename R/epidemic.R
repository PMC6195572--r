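#' Simulate a discrete-time SIR/SIS epidemic on an edge sequence
#'
#' The epidemic is driven by the flattened edge sequence (event clock): at
#' step `t` only the active edge `(u, v)_t` can transmit.  Two sub-steps per
#' step, both conditioned on the states at `t - 1`:
#' 1. if exactly one endpoint was infected and the other susceptible, the
#'    susceptible endpoint becomes infected with probability `beta`;
#' 2. every node that was infected at `t - 1` recovers with probability
#'    `gamma` (SIR: to R; SIS: back to S).
#' A node infected at step `t` therefore cannot recover at step `t`, while a
#' node may transmit and recover in the same step.  `X(t)` is recorded after
#' both sub-steps, for `t = 0..E`.
#'
#' @param x a `temporal_edges` object or a [token_sequence()] (whose alphabet
#'   supplies the node pairs).
#' @param model `"SIR"` or `"SIS"`.
#' @param beta per-contact infection probability in `[0, 1]`.
#' @param gamma per-step recovery probability in `[0, 1]`.
#' @param seeds explicit node ids to infect initially; overrides `n_seeds`.
#' @param n_seeds number of uniformly random initially infected nodes
#'   (default 1).
#' @param seed RNG seed.
#' @param keep_states if `TRUE`, keep the full `(E+1) x N` state matrix
#'   (0 = S, 1 = I, 2 = R).
#' @return an object of class `epidemic_trajectory` with the infected curve
#'   `X` (length `E + 1`, `X[1]` is `t = 0`), the per-step compartment counts
#'   matrix `counts` (columns S, I, R), the seed nodes, `N`, `E` and
#'   optionally `states`.
#' @export
simulate_epidemic <- function(x, model = c("SIR", "SIS"), beta, gamma,
                              seeds = NULL, n_seeds = 1L, seed = NULL,
                              keep_states = FALSE) {
  model <- match.arg(toupper(model[1L]), c("SIR", "SIS"))
  stopifnot(beta >= 0, beta <= 1, gamma >= 0, gamma <= 1)
  ev <- edge_events(x)
  N <- ev$N; E <- length(ev$u)
  run_seeded(seed, {
    seed_nodes <- if (!is.null(seeds)) {
      idx <- match(seeds, ev$nodes)
      if (anyNA(idx)) stop("unknown node id in seeds: ",
                           paste(seeds[is.na(idx)], collapse = ", "))
      idx
    } else sample.int(N, n_seeds)
    run_epidemic_core(ev$u, ev$v, N, model, beta, gamma, seed_nodes,
                      keep_states, ev$nodes)
  })
}

# normalize input to internal 1..N node indices
edge_events <- function(x) {
  if (inherits(x, "token_sequence")) {
    u <- x$alphabet[x$tokens + 1L, 1L]
    v <- x$alphabet[x$tokens + 1L, 2L]
    nodes <- sort(unique(c(x$alphabet[, 1L], x$alphabet[, 2L])))
  } else if (inherits(x, "temporal_edges")) {
    u <- x$u; v <- x$v
    nodes <- sort(unique(c(u, v)))
  } else stop("x must be a temporal_edges or token_sequence object")
  list(u = match(u, nodes), v = match(v, nodes), nodes = nodes,
       N = length(nodes))
}

run_epidemic_core <- function(uu, vv, N, model, beta, gamma, seed_nodes,
                              keep_states, nodes) {
  E <- length(uu)
  state <- integer(N)                  # 0 = S, 1 = I, 2 = R
  state[seed_nodes] <- 1L
  X <- integer(E + 1L)
  counts <- matrix(0L, E + 1L, 3L, dimnames = list(NULL, c("S", "I", "R")))
  states <- if (keep_states) matrix(0L, E + 1L, N) else NULL
  X[1L] <- sum(state == 1L)
  counts[1L, ] <- c(sum(state == 0L), X[1L], sum(state == 2L))
  if (keep_states) states[1L, ] <- state
  rec_to <- if (model == "SIR") 2L else 0L
  for (t in seq_len(E)) {
    u <- uu[t]; v <- vv[t]
    su <- state[u]; sv <- state[v]
    newly <- 0L
    if (su == 0L && sv == 1L) {
      if (stats::runif(1L) <= beta) newly <- u
    } else if (su == 1L && sv == 0L) {
      if (stats::runif(1L) <= beta) newly <- v
    }
    if (gamma > 0) {
      inf_prev <- which(state == 1L)   # infected at t - 1
      if (length(inf_prev)) {
        rec <- inf_prev[stats::runif(length(inf_prev)) <= gamma]
        state[rec] <- rec_to
      }
    }
    if (newly > 0L) state[newly] <- 1L
    ni <- sum(state == 1L)
    X[t + 1L] <- ni
    counts[t + 1L, ] <- c(sum(state == 0L), ni, sum(state == 2L))
    if (keep_states) states[t + 1L, ] <- state
  }
  structure(list(model = model, beta = beta, gamma = gamma,
                 seed_nodes = nodes[seed_nodes], X = X, counts = counts,
                 final_state = stats::setNames(state, nodes),
                 states = states, N = N, E = E),
            class = "epidemic_trajectory")
}

#' @export
print.epidemic_trajectory <- function(x, ...) {
  cat(x$model, " trajectory: N = ", x$N, ", E = ", x$E,
      ", beta = ", x$beta, ", gamma = ", x$gamma, "\n", sep = "")
  cat("  seeds: ", paste(x$seed_nodes, collapse = ", "),
      "; final infected: ", x$X[x$E + 1L],
      "; ever infected: ", sum(x$final_state != 0L), "\n", sep = "")
  invisible(x)
}

#' Ensemble-averaged infected curve
#'
#' Runs `realizations` independent epidemics and returns the mean number of
#' infected nodes per step with its standard error (standard deviation of
#' the mean).  When several sequences are supplied (e.g. surrogate
#' replicates), each realization draws one sequence at random, so both the
#' network model and the dynamics are resampled.  Seed nodes are redrawn per
#' realization unless `seeds` is given.
#'
#' @param x a single `temporal_edges`/`token_sequence`, or a list of
#'   `token_sequence` objects of equal length.
#' @param model,beta,gamma,seeds,n_seeds as in [simulate_epidemic()].
#' @param realizations number of independent runs (default 100).
#' @param seed master seed.
#' @return a `data.frame` with columns `t` (0-based event clock), `mean_X`
#'   and `stderr_X` (0 when `realizations == 1`).
#' @export
ensemble_infected_curve <- function(x, model = c("SIR", "SIS"), beta, gamma,
                                    realizations = 100L, seeds = NULL,
                                    n_seeds = 1L, seed = NULL) {
  xs <- if (inherits(x, c("temporal_edges", "token_sequence"))) list(x) else x
  E <- unique(vapply(xs, function(s)
    if (inherits(s, "token_sequence")) s$E else nrow(s), 0L))
  if (length(E) != 1L) stop("all sequences must have equal length")
  run_seeded(seed, {
    run_seeds <- draw_run_seeds(realizations)
    which_seq <- if (length(xs) > 1L)
      sample.int(length(xs), realizations, replace = TRUE)
    else rep(1L, realizations)
    Xs <- vapply(seq_len(realizations), function(r) {
      simulate_epidemic(xs[[which_seq[r]]], model = model, beta = beta,
                        gamma = gamma, seeds = seeds, n_seeds = n_seeds,
                        seed = run_seeds[r])$X
    }, numeric(E + 1L))
    mean_X <- rowMeans(Xs)
    stderr_X <- if (realizations > 1L)
      apply(Xs, 1L, stats::sd) / sqrt(realizations)
    else rep(0, E + 1L)
    data.frame(t = 0:E, mean_X = mean_X, stderr_X = stderr_X)
  })
}
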