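# compact synthetic PSM set for training tests
toy_psms <- function(n_spectra = 400, n_features = 4, effect = c(3, 0, 0, 0),
                     prop_correct = 0.5, seed = 1) {
  withr::with_seed(seed, {
    correct <- runif(n_spectra) < prop_correct
    feat_t <- matrix(rnorm(n_spectra * n_features), n_spectra)
    feat_t[correct, ] <- sweep(feat_t[correct, , drop = FALSE], 2, effect, "+")
    feat_d <- matrix(rnorm(n_spectra * n_features), n_spectra)
  })
  nm <- sprintf("f%d", seq_len(n_features))
  build <- function(feat, is_target) {
    df <- data.frame(spec_id = sprintf("s%04d", seq_len(n_spectra)),
                     is_target = is_target, scan = seq_len(n_spectra))
    for (j in seq_len(n_features)) df[[nm[j]]] <- feat[, j]
    df$peptide <- paste0("-.", sprintf("PEPTIDEK%04d%s", seq_len(n_spectra),
                                       if (is_target) "T" else "D"), ".-")
    df$proteins <- as.list(sprintf("P%04d", seq_len(n_spectra)))
    df
  }
  psms <- rbind(build(feat_t, TRUE), build(feat_d, FALSE))
  attr(psms, "feature_names") <- nm
  class(psms) <- c("psm_set", "data.frame")
  psms
}

test_that("subset sampling keeps whole spectra and is deterministic", {
  psms <- toy_psms(n_spectra = 10)
  sub <- subset_sample(psms, 6, seed = 3)
  expect_equal(nrow(sub), 6)
  expect_equal(length(unique(sub$spec_id)), 3)
  # no orphaned pair: every selected spectrum contributes both PSMs
  expect_true(all(table(sub$spec_id) == 2))
  expect_identical(subset_sample(psms, 6, seed = 3), sub)
  expect_false(identical(subset_sample(psms, 6, seed = 4)$spec_id,
                         sub$spec_id))
  # subset_size = total is the identity
  expect_identical(subset_sample(psms, nrow(psms), seed = 1), psms)
  expect_warning(big <- subset_sample(psms, nrow(psms) + 5), "all")
  expect_equal(nrow(big), nrow(psms))
})

test_that("initial direction finds the informative feature and its sign", {
  psms <- toy_psms(n_spectra = 500, effect = c(3, 0, 0, 0), seed = 2)
  X <- as.matrix(psms[, attr(psms, "feature_names")])
  init <- initial_direction(X, psms$is_target)
  expect_equal(init$feature, 1L)
  expect_equal(init$sign, 1)
  # negated informative feature: same index, negative sign
  X2 <- X
  X2[, 1] <- -X2[, 1]
  init2 <- initial_direction(X2, psms$is_target)
  expect_equal(init2$feature, 1L)
  expect_equal(init2$sign, -1)
  # pure noise, nothing reaches q <= 0.01: tie-break to feature 1, positive
  withr::with_seed(6, {
    Xn <- matrix(rnorm(200 * 3), 200)
    init3 <- initial_direction(Xn, rep(c(TRUE, FALSE), 100))
  })
  expect_equal(init3$n_positives, 0L)
  expect_equal(init3$feature, 1L)
  expect_equal(init3$sign, 1)
})

test_that("the primal SVM separates linearly separable data and matches libsvm", {
  skip_if_not_installed("e1071")
  withr::with_seed(4, {
    n <- 60
    X <- rbind(matrix(rnorm(n * 2, 4), n), matrix(rnorm(n * 2, -4), n))
    y <- rep(c(1, -1), each = n)
    Xb <- cbind(X, 1)
    w <- pickedfdr:::svm_l2_primal(Xb, y, rep(10, 2 * n))
    expect_true(all(sign(drop(Xb %*% w)) == y))
    # direction agrees with an independent SVM implementation
    m <- e1071::svm(X, factor(y), kernel = "linear", cost = 10,
                    scale = FALSE)
    w_ref <- drop(t(m$coefs) %*% m$SV)
    cosine <- sum(w[1:2] * w_ref) / sqrt(sum(w[1:2]^2) * sum(w_ref^2))
    expect_gt(abs(cosine), 0.95)
  })
})

test_that("rescoring separates classes and is deterministic given the seed", {
  psms <- toy_psms(n_spectra = 600, effect = c(2.5, 1.5, 0, 0), seed = 9)
  fit <- rescore(psms, train_config(iterations = 5, seed = 1))
  expect_s3_class(fit, "rescore_fit")
  # correct-class separation: more identifications than the initial
  # single-feature direction would find alone
  n_init <- max(vapply(fit$initial, `[[`, integer(1L), "n_positives"))
  n_fit <- sum(fit$psms$is_target & fit$psms$q_value <= 0.01)
  expect_gte(n_fit, 0.9 * n_init)
  fit2 <- rescore(psms, train_config(iterations = 5, seed = 1))
  expect_identical(fit$psms$score, fit2$psms$score)
  expect_identical(fit$weights, fit2$weights)
  # methods work
  expect_named(coef(fit), c(attr(psms, "feature_names"), "(bias)"))
  expect_output(print(fit), "rescoring fit")
  expect_output(print(summary(fit)), "per-fold weights")
  pred <- predict(fit, psms)
  expect_equal(length(pred), nrow(psms))
})

test_that("zero iterations returns the initial direction", {
  psms <- toy_psms(n_spectra = 300, seed = 5)
  fit <- rescore(psms, train_config(iterations = 0, seed = 2))
  for (k in seq_along(fit$initial)) {
    w <- fit$weights[, k]
    init <- fit$initial[[k]]
    expect_equal(unname(w[init$feature]), init$sign)
    expect_equal(sum(w != 0), 1L)
  }
})

test_that("training positives tend not to decrease over iterations", {
  # Monte-Carlo: the semi-supervised refinement should (almost always) find
  # at least as many positives as the initial direction
  good <- 0L
  for (s in 1:10) {
    psms <- toy_psms(n_spectra = 400, effect = c(2, 1, 1, 0), seed = 100 + s)
    fit <- rescore(psms, train_config(iterations = 4, seed = s))
    n_init <- stats::median(vapply(fit$initial, `[[`, integer(1L),
                                   "n_positives"))
    n_fit <- sum(fit$psms$is_target & fit$psms$q_value <= 0.01)
    if (n_fit >= n_init) good <- good + 1L
  }
  expect_gte(good, 8L)
})

test_that("subset-average scoring equals single-vector ranking when folds agree", {
  psms <- toy_psms(n_spectra = 200, seed = 12)
  fit <- rescore(psms, train_config(iterations = 2, seed = 1))
  # force identical vectors and normalizations across folds
  fit$weights <- matrix(fit$weights[, 1], nrow(fit$weights), 3)
  fit$normalization <- rep(fit$normalization[1], 3)
  avg <- predict(fit, psms)
  single <- (drop(cbind(sweep(sweep(as.matrix(
    psms[, fit$feature_names]), 2, fit$center), 2, fit$scale, "/"), 1) %*%
      fit$weights[, 1]) - fit$normalization[[1]]["decoy_mean"]) /
    fit$normalization[[1]]["decoy_sd"]
  expect_equal(order(avg), order(unname(single)))
  expect_equal(avg, unname(single))
})

test_that("PIN files round-trip bit-identically through the reader and writer", {
  psms <- toy_psms(n_spectra = 25, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".pin")
  f2 <- withr::local_tempfile(fileext = ".pin")
  write_pin(psms, f1)
  back <- read_pin(f1)
  expect_equal(back$spec_id, psms$spec_id)
  expect_equal(back$is_target, psms$is_target)
  expect_equal(back$f1, psms$f1, tolerance = 1e-15)
  expect_equal(back$peptide, psms$peptide)
  expect_equal(back$proteins, psms$proteins)
  write_pin(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # DefaultDirection line is tolerated
  lines <- readLines(f1)
  writeLines(c(lines[1],
               paste(c("DefaultDirection", "-", "-", rep("1", 4), "-", "-"),
                     collapse = "\t"), lines[-1]), f2)
  expect_equal(nrow(read_pin(f2)), nrow(psms))
})
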