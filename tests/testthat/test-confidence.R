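test_that("target-decoy q-values follow the +1 convention with monotonization", {
  expect_equal(td_qvalues(c(10, 9, 8, 7, 8.5, 6), c(T, T, T, T, F, F)),
               c(0.5, 0.5, 0.5, 0.5, 0.5, 0.75))
  # no decoys: every target gets (0 + 1) / n at the loosest threshold
  expect_equal(td_qvalues(c(3, 2, 1), c(T, T, T)), rep(1 / 3, 3))
  # all decoys above all targets: capped at 1
  q <- td_qvalues(c(1:10 + 100, 1:10), c(rep(F, 10), rep(T, 10)))
  expect_equal(q[11:20], rep(1, 10))
  expect_error(td_qvalues(1:3, rep(FALSE, 3)), "target")
})

test_that("q-values agree with the exhaustive-threshold oracle on random instances", {
  withr::with_seed(123, {
    for (rep in 1:60) {
      n <- sample(2:60, 1)
      score <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
      is_target <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(is_target)) is_target[1] <- TRUE
      expect_equal(td_qvalues(score, is_target),
                   oracle_qvalues(score, is_target))
    }
  })
})

test_that("tied scores are accepted or rejected together", {
  q <- td_qvalues(c(5, 5, 5, 3), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(q[1], q[2])
  expect_equal(q[1], q[3])
})

test_that("PEP estimates separate label-pure bins and respect monotonicity", {
  withr::with_seed(1, {
    score <- c(rnorm(200, 10), rnorm(200, 0))
    is_target <- c(rep(TRUE, 200), rep(FALSE, 200))
    pep <- estimate_peps(score, is_target, n_bins = 2)
    expect_equal(unique(pep[1:200]), 0)
    expect_equal(unique(pep[201:400]), 1)
    # identical distributions: PEPs near 1 everywhere
    s2 <- rnorm(2000)
    l2 <- rep(c(TRUE, FALSE), 1000)
    pep2 <- estimate_peps(s2, l2)
    expect_gt(mean(pep2), 0.85)
    # monotone non-increasing in score for arbitrary input
    s3 <- rnorm(500)
    l3 <- runif(500) < plogis(s3)
    pep3 <- estimate_peps(s3, l3, n_bins = 10)
    o <- order(s3)
    expect_true(all(diff(pep3[o]) <= 1e-12))
    expect_true(all(pep3 >= 0 & pep3 <= 1))
  })
  expect_error(estimate_peps(1:10, rep(c(T, F), 5), n_bins = 0), "n_bins")
})

test_that("PEPs are consistent with FDR: mean PEP below a cutoff bounds the error rate", {
  withr::with_seed(77, {
    score <- c(rnorm(3000, 2.5), rnorm(3000))
    is_target <- c(rep(TRUE, 3000), rep(FALSE, 3000))
    pep <- estimate_peps(score, is_target)
    for (cc in c(0.05, 0.2, 0.5)) {
      sel <- is_target & pep <= cc
      expect_lte(mean(pep[sel]), cc + 0.02)
    }
  })
})

test_that("empirical p-values count decoys at or above the score with +1 smoothing", {
  expect_equal(empirical_pvalues(5, c(1, 2, 3)), 0.25)
  expect_equal(empirical_pvalues(0, c(1, 2, 3)), 1)
  expect_equal(empirical_pvalues(1000, seq_len(999)), 1 / 1000)
  # ties: a score equal to a decoy counts that decoy
  expect_equal(empirical_pvalues(2, c(1, 2, 3)), 0.75)
  expect_error(empirical_pvalues(1, numeric(0)), "non-empty")
})

test_that("Fisher's combination matches chi-square closed forms and integration", {
  # closed form for 4 df: (1 + X/2) exp(-X/2)
  x <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(fisher_combine(c(0.5, 0.5)), (1 + x / 2) * exp(-x / 2),
               tolerance = 1e-12)
  expect_equal(round(fisher_combine(c(0.5, 0.5)), 4), 0.5966)
  # identity at k = 1 (2 df closed form exp(-X/2) = p)
  for (p in c(0.01, 0.2, 0.77, 1)) expect_equal(fisher_combine(p), p)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  # numerical integration of the chi-square density for k <= 5
  withr::with_seed(3, {
    for (k in 2:5) {
      p <- runif(k, 0.01, 1)
      x <- -2 * sum(log(p))
      num <- integrate(function(t) dchisq(t, df = 2 * k), x, Inf,
                       rel.tol = 1e-12)$value
      expect_equal(fisher_combine(p), num, tolerance = 1e-9)
    }
  })
  expect_error(fisher_combine(numeric(0)))
  expect_error(fisher_combine(c(0.5, 0)))
})

test_that("q-values are calibrated when decoys and incorrect targets are exchangeable", {
  # Fig. 3-style property at the score level: the q-value at a threshold
  # matches the true false-positive fraction within binomial error
  withr::with_seed(9, {
    n_true <- 2000; n_null <- 4000
    score <- c(rnorm(n_true, 3.5), rnorm(n_null), rnorm(n_null))
    is_target <- c(rep(TRUE, n_true + n_null), rep(FALSE, n_null))
    truth <- c(rep(TRUE, n_true), rep(FALSE, 2 * n_null))
    q <- td_qvalues(score, is_target)
    for (thr in c(0.02, 0.05, 0.1)) {
      acc <- is_target & q <= thr
      realized <- mean(!truth[acc])
      se <- sqrt(thr * (1 - thr) / sum(acc))
      expect_lt(abs(realized - thr), 4 * se + 1 / sum(acc))
    }
  })
})

test_that("confidence tables carry q, PEP and p-value columns sorted by score", {
  withr::with_seed(2, {
    tab <- data.frame(id = sprintf("e%d", 1:100),
                      score = c(rnorm(60, 2), rnorm(40)),
                      is_target = c(rep(TRUE, 60), rep(FALSE, 40)))
    ct <- confidence_table(tab)
    expect_true(!is.unsorted(rev(ct$score)))
    expect_true(all(diff(ct$q_value) >= 0))   # q non-increasing in score
    expect_true(all(ct$p_value > 0 & ct$p_value <= 1))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_confidence_tsv(ct, f)
    back <- read.delim(f)
    expect_equal(nrow(back), 100)
    expect_equal(back$score, ct$score)
  })
})
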