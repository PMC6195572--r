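test_that("transition counts follow the counting contract", {
  # tokens A,B,A,B,A at order 1: a_{B,A} = a_{A,B} = 2, k_A = k_B = 2
  cnt <- count_transitions(ts(c(0, 1, 0, 1, 0)), 1)
  expect_equal(sort(cnt$count), c(2L, 2L))
  expect_equal(unname(cnt$k[c("0", "1")]), c(2, 2))
  expect_equal(cnt$n_transitions, 4L)

  # order 0 on A,A,B,A
  cnt0 <- count_transitions(ts(c(0, 0, 1, 0)), 0)
  expect_equal(cnt0$count[match(c(0L, 1L), cnt0$token)], c(3L, 1L))
  expect_equal(unname(cnt0$k), 4)

  # conservation: order-0 counts sum to E; order-n to E - n
  set.seed(2)
  x <- ts(sample(0:3, 60, replace = TRUE))
  for (n in 0:3) {
    cn <- count_transitions(x, n)
    expect_equal(sum(cn$count), 60L - n)
    expect_equal(sum(cn$k), 60 - n)
    # per-memory totals match their own counts
    for (i in seq_along(cn$k))
      expect_equal(unname(cn$k[i]),
                   sum(cn$count[cn$mem == names(cn$k)[i]]))
  }
  expect_error(count_transitions(ts(c(0, 1)), 2), "shorter than order")
})

test_that("MLE transition probabilities are count ratios maximizing the likelihood", {
  cnt <- count_transitions(ts(c(0, 0, 1, 0)), 0)
  p <- mle_transitions(cnt)
  expect_equal(unname(p$p[[1]]), c(0.75, 0.25))  # order 0: single "" memory

  # degenerate row
  p1 <- mle_transitions(count_transitions(ts(rep(0L, 6), D = 2), 0))
  expect_equal(unname(p1$p[[1]]), 1)

  # rows sum to 1, and no small perturbation increases the likelihood
  set.seed(3)
  x <- ts(sample(0:2, 80, replace = TRUE))
  cnt <- count_transitions(x, 1)
  p <- mle_transitions(cnt)
  loglik <- function(pl) {
    sum(vapply(seq_along(cnt$count), function(i) {
      cnt$count[i] * log(pl[[cnt$mem[i]]][as.character(cnt$token[i])])
    }, 0))
  }
  base <- loglik(p$p)
  for (m in names(p$p)) {
    expect_equal(sum(p$p[[m]]), 1, tolerance = 1e-12)
    row <- p$p[[m]]
    if (length(row) < 2) next
    for (j in seq_along(row)) {
      pert <- row
      pert[j] <- pert[j] + 1e-3
      pert <- pert / sum(pert)
      p2 <- p$p; p2[[m]] <- pert
      expect_lte(loglik(p2), base + 1e-12)
    }
  }
})

test_that("stationary marginal likelihood matches an integration oracle", {
  # A,A,B,A, n = 0, D = 2: closed form gives 1/20; independent oracle
  # integrates p^3 (1-p) over the 1-simplex with the uniform (D-1)! prior
  cnt <- count_transitions(ts(c(0, 0, 1, 0)), 0)
  lm <- log_marginal_stationary(cnt, D = 2)
  expect_equal(exp(lm), 1 / 20, tolerance = 1e-12)
  oracle <- stats::integrate(function(p) factorial(1) * p^3 * (1 - p),
                             0, 1)$value
  expect_equal(exp(lm), oracle, tolerance = 1e-8)

  # empty transition set has probability 1
  expect_equal(log_marginal_stationary(count_transitions(ts(c(0, 1)), 1), 2),
               lgamma(2) - lgamma(3))  # one transition, not empty
  s1 <- ts(0L, D = 2)
  expect_error(count_transitions(s1, 1), "shorter")

  # label-permutation invariance
  set.seed(4)
  x <- sample(0:2, 50, replace = TRUE)
  perm <- c(2L, 0L, 1L)
  for (n in 0:2) {
    a <- log_marginal_stationary(count_transitions(ts(x, D = 3), n), 3)
    b <- log_marginal_stationary(count_transitions(ts(perm[x + 1], D = 3), n), 3)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("marginal likelihood is normalized over continuations", {
  # D = 2, E = 6: summed over all continuations of a fixed length-n prefix
  for (n in 0:2) {
    prefix <- c(0L, 1L)[seq_len(n)]
    conts <- as.matrix(expand.grid(rep(list(0:1), 6 - n)))
    tot <- sum(apply(conts, 1, function(cc) {
      cnt <- count_transitions(token_sequence(c(prefix, cc), D = 2), n)
      exp(log_marginal_stationary(cnt, 2))
    }))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("order posterior normalizes, selects the right order, and is stable", {
  s <- ts(c(0, 1, 0, 1, 0, 1, 0, 1))
  op0 <- order_posterior(s, n_max = 0)
  expect_equal(unname(op0$posterior), 1)

  op <- order_posterior(s, n_max = 3)
  expect_equal(sum(op$posterior), 1, tolerance = 1e-12)
  expect_error(order_posterior(s, n_max = 8), "smaller")

  # a strongly periodic sequence demands memory: order 0 is crushed
  s2 <- ts(rep(c(0L, 1L), 200))
  op2 <- order_posterior(s2, n_max = 2)
  expect_gte(op2$mode, 1L)
  expect_gt(op2$log_evidence["1"] - op2$log_evidence["0"], 100)

  # shared-prefix variant conditions all orders on the same data
  ops <- order_posterior(s2, n_max = 2, shared_prefix = TRUE)
  expect_equal(sum(ops$posterior), 1, tolerance = 1e-12)
  expect_gte(ops$mode, 1L)

  # planted order-1 chain, D = 3: posterior mode recovers n = 1
  pm <- make_planted_model(D = 3, n = 1, segment_lengths = 4000,
                           alpha = 0.1, seed = 21)
  g <- generate_planted(pm, seed = 22)
  expect_equal(order_posterior(g$seq, n_max = 2)$mode, 1L)
})

test_that("fitted order-0 probabilities recover planted ones within 0.05", {
  pm <- make_planted_model(D = 5, n = 0, segment_lengths = 10000,
                           alpha = 1, seed = 31)
  g <- generate_planted(pm, seed = 32)
  fit <- fit_markov(g$seq, order = 0)
  phat <- rep(0, 5)
  row <- coef(fit)$p[[1]]
  phat[as.integer(names(row)) + 1] <- row
  expect_lt(max(abs(phat - pm$matrices[[1]][1, ])), 0.05)
})

test_that("fit_markov selects by evidence and exposes methods", {
  s2 <- ts(rep(c(0L, 1L), 100))
  fit <- fit_markov(s2, n_max = 1)
  expect_s3_class(fit, "markov_fit")
  expect_equal(fit$order, 1L)
  expect_equal(as.numeric(logLik(fit)), fit$log_evidence)
  expect_output(print(fit), "order n")
  expect_output(summary(fit), "posterior")
  expect_named(coef(fit), c("order", "p", "D"), ignore.order = TRUE)
})
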