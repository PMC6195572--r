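test_that("segmented counts attribute transitions and alphabets correctly", {
  s <- ts(c(0, 1, 0, 1))
  seg <- segmentation(2, 4)
  sc <- segment_counts(s, seg, 0)
  for (l in 1:2) {
    expect_equal(sort(sc$segments[[l]]$count), c(1L, 1L))
    expect_equal(sc$segments[[l]]$D_l, 2L)
  }

  # M = 0 reduces to plain transition counts with D_0 = D
  seg0 <- segmentation(integer(0), 4)
  sc0 <- segment_counts(s, seg0, 0)
  cnt <- count_transitions(s, 0)
  expect_equal(sort(sc0$segments[[1]]$count), sort(cnt$count))
  expect_equal(sc0$segments[[1]]$D_l, s$D)

  # conservation at E - n for arbitrary segmentations; memories cross
  # boundaries unchanged
  set.seed(7)
  x <- ts(sample(0:3, 50, replace = TRUE))
  for (n in 0:2) {
    for (rep in 1:5) {
      b <- sort(sample(1:49, sample(0:4, 1)))
      sc <- segment_counts(x, segmentation(b, 50), n)
      expect_equal(sum(unlist(lapply(sc$segments, `[[`, "count"))), 50L - n)
    }
  }
  expect_error(segmentation(50, 50), "1..E-1")
  expect_error(segmentation(0, 50), "1..E-1")
})

test_that("joint likelihood matches the closed form and the M = 0 identity", {
  # A,A,B,A, M = 0, n = 0, D = 2: 2^-2 * (24/120) * (6/120) = 0.0025
  s <- ts(c(0, 0, 1, 0))
  seg <- segmentation(integer(0), 4)
  lj <- log_joint_likelihood(segment_counts(s, seg, 0), seg)
  expect_equal(exp(lj), 0.0025, tolerance = 1e-12)

  # identity: log_joint(M=0) = log_marginal - D log 2 - log(E+1) whenever
  # every token appears
  set.seed(8)
  for (rep in 1:10) {
    x <- ts(sample(0:2, 30, replace = TRUE))
    n <- sample(0:2, 1)
    seg <- segmentation(integer(0), 30)
    lhs <- log_joint_likelihood(segment_counts(x, seg, n), seg)
    rhs <- log_marginal_stationary(count_transitions(x, n), x$D) -
      x$D * log(2) - log(31)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }

  # token-relabelling invariance
  set.seed(9)
  x <- sample(0:2, 40, replace = TRUE)
  perm <- c(1L, 2L, 0L)
  seg <- segmentation(c(13, 27), 40)
  a <- log_joint_likelihood(segment_counts(ts(x, D = 3), seg, 1), seg)
  b <- log_joint_likelihood(segment_counts(ts(perm[x + 1], D = 3), seg, 1), seg)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("move proposals cover the three types with the stated probabilities", {
  # E = 2, M = 0: the only applicable split has the unique boundary {1}
  set.seed(10)
  seg2 <- segmentation(integer(0), 2)
  repeat {
    mv <- propose_move(seg2)
    if (mv$move == "split") break
  }
  expect_false(mv$rejected)
  expect_equal(mv$seg$boundaries, 1L)
  expect_equal(mv$log_ratio, log(1))

  # merge/shift at M = 0 are flagged rejections
  repeat {
    mv <- propose_move(seg2)
    if (mv$move != "split") break
  }
  expect_true(mv$rejected)
  expect_equal(mv$seg$boundaries, integer(0))

  # move types are drawn 1/3 each
  set.seed(11)
  seg <- segmentation(c(10, 20), 30)
  moves <- vapply(1:100000, function(i) propose_move(seg)$move, "")
  freq <- as.numeric(table(moves)) / 100000
  expect_length(freq, 3L)
  expect_lt(max(abs(freq - 1 / 3)), 0.01)
})

test_that("Hastings ratios make split/merge mutually consistent", {
  # split of a length-L segment carries log(L-1); the reverse merge -log(L-1)
  set.seed(12)
  x <- ts(sample(0:1, 12, replace = TRUE))
  for (rep in 1:200) {
    b <- sort(sample(1:11, sample(0:3, 1)))
    seg <- segmentation(b, 12)
    mv <- propose_move(seg)
    if (mv$rejected) next
    if (mv$move == "split") {
      cut <- setdiff(mv$seg$boundaries, seg$boundaries)
      nb <- sort(c(seg$boundaries, 0L, 12L))
      lo <- max(nb[nb < cut]); hi <- min(nb[nb > cut])
      expect_equal(mv$log_ratio, log(hi - lo - 1))
    } else if (mv$move == "merge") {
      gone <- setdiff(seg$boundaries, mv$seg$boundaries)
      nb <- sort(c(mv$seg$boundaries, 0L, 12L))
      lo <- max(nb[nb < gone]); hi <- min(nb[nb > gone])
      expect_equal(mv$log_ratio, -log(hi - lo - 1))
    } else {
      expect_equal(mv$log_ratio, 0)
    }
    # detailed balance: a(l->l') / a(l'->l) = exp(dlp + log_ratio)
    lp <- function(sg) log_joint_likelihood(segment_counts(x, sg, 0), sg)
    dlp <- lp(mv$seg) - lp(seg)
    a_fwd <- mh_accept_prob(lp(mv$seg), lp(seg), mv$log_ratio)
    a_rev <- mh_accept_prob(lp(seg), lp(mv$seg), -mv$log_ratio)
    expect_equal(a_fwd / a_rev, exp(dlp + mv$log_ratio), tolerance = 1e-9)
  }
})

test_that("MH acceptance probability implements the criterion", {
  expect_equal(mh_accept_prob(-5, -5, 0), 1)
  expect_equal(mh_accept_prob(-5 - log(2), -5, 0), 0.5)
  expect_equal(mh_accept_prob(-2, -10, 0), 1)      # improvements always accepted
  expect_equal(mh_accept_prob(-5, -5, log(3)), 1)  # ratio can push past 1
})

test_that("exact enumeration oracle normalizes and agrees with the sampler", {
  s3 <- ts(c(0, 1, 0))
  ex3 <- exact_segmentation_posterior(s3, 0)
  expect_equal(nrow(ex3), 4L)  # 2^(E-1)
  expect_equal(sum(ex3$prob), 1, tolerance = 1e-12)
  expect_error(exact_segmentation_posterior(ts(rep(0:1, 10)), 0),
               "infeasible")

  # sampler MAP equals enumeration argmax on a tiny sequence
  set.seed(13)
  s10 <- ts(c(rep(0L, 5), rep(1L, 5)))
  ex <- exact_segmentation_posterior(s10, 0)
  fit <- fit_changepoints(s10, order = 0, runs = 3, seed = 14)
  best <- ex$boundaries[which.max(ex$log_joint)]
  got <- paste(fit$boundaries, collapse = ",")
  expect_equal(got, best)
  expect_equal(fit$log_joint, max(ex$log_joint), tolerance = 1e-9)

  # long-run visit frequencies match the exact posterior (E = 12)
  set.seed(15)
  s12 <- ts(sample(0:1, 12, replace = TRUE), D = 2)
  ex12 <- exact_segmentation_posterior(s12, 0)
  freq <- mh_visit_frequencies(s12, 0, 2e5, seed = 16)
  tv <- 0.5 * sum(abs(freq - ex12$prob))
  expect_lt(tv, 0.05)
})

test_that("fitted model is internally consistent and seed-reproducible", {
  pm <- make_planted_model(D = 5, n = 0, segment_lengths = c(600, 600),
                           alpha = 0.1, seed = 41)
  g <- generate_planted(pm, seed = 42)
  fit <- fit_changepoints(g$seq, order = 0, runs = 3, seed = 43)

  # reported log joint equals recomputation from its own counts
  expect_equal(fit$log_joint,
               log_joint_likelihood(fit$counts, fit$segmentation),
               tolerance = 1e-9)
  # counts stored in the fit equal a from-scratch segmentation count
  sc <- segment_counts(g$seq, fit$segmentation, 0)
  for (l in seq_along(sc$segments)) {
    o <- order(sc$segments[[l]]$mem, sc$segments[[l]]$token)
    f <- order(fit$counts$segments[[l]]$mem, fit$counts$segments[[l]]$token)
    expect_identical(sc$segments[[l]]$count[o],
                     fit$counts$segments[[l]]$count[f])
    expect_identical(sc$segments[[l]]$D_l, fit$counts$segments[[l]]$D_l)
  }
  # per-segment MLE rows normalize
  for (p in coef(fit))
    for (row in p$p) expect_equal(sum(row), 1, tolerance = 1e-12)

  # bit-for-bit reproducibility under the same master seed
  fit2 <- fit_changepoints(g$seq, order = 0, runs = 3, seed = 43)
  expect_identical(fit$boundaries, fit2$boundaries)
  expect_identical(fit$log_joint, fit2$log_joint)
  expect_identical(fit$log_joint_runs, fit2$log_joint_runs)
})

test_that("homogeneous data yield no spurious change points", {
  pm <- make_planted_model(D = 5, n = 0, segment_lengths = 5000,
                           alpha = 1e6, seed = 51)  # near-uniform rows
  g <- generate_planted(pm, seed = 52)
  fit <- fit_changepoints(g$seq, order = 0, runs = 3, seed = 53)
  expect_equal(fit$M, 0L)
  expect_equal(estimate_q(fit), 0)
})

test_that("odds ratio and q-hat follow their definitions", {
  pm <- make_planted_model(D = 4, n = 0, segment_lengths = c(500, 500),
                           alpha = 0.1, seed = 61)
  g <- generate_planted(pm, seed = 62)
  fit <- fit_changepoints(g$seq, order = 0, runs = 3, seed = 63)
  base <- fit_stationary_baseline(g$seq, order = 0)
  expect_equal(base$M, 0L)
  lam <- posterior_odds_ratio(fit, base)
  expect_equal(lam, exp(fit$log_joint - base$log_joint))
  expect_gt(lam, 1)  # planted two-regime data favour the segmented model
  expect_equal(posterior_odds_ratio(fit, fit), 1)

  expect_equal(estimate_q(segmentation(c(1, 5, 9), 1000)), 0.003)
  expect_equal(estimate_q(segmentation(integer(0), 10)), 0)
  expect_equal(estimate_q(segmentation(1:9, 10)), 0.9)

  other <- fit_stationary_baseline(ts(c(0, 1, 0)), 0)
  expect_error(posterior_odds_ratio(fit, other), "different lengths")
})
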