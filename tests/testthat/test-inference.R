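make_evidence <- function(group_id, score, pep = NULL, p_value = NULL,
                          q_value = NULL, is_target = TRUE) {
  n <- length(score)
  data.frame(group_id = rep_len(group_id, n),
             peptide = sprintf("PEP%d", seq_len(n)),
             score = score,
             q_value = if (is.null(q_value)) rep(0.001, n) else q_value,
             pep = if (is.null(pep)) rep(0.5, n) else pep,
             p_value = if (is.null(p_value)) rep(0.5, n) else p_value,
             is_target = rep_len(is_target, n),
             stringsAsFactors = FALSE)
}

test_that("the four protein scorers aggregate peptide evidence as defined", {
  ev <- make_evidence("G1", c(3.1, 2.0, 0.5))
  expect_equal(score_protein_groups(ev, "best_peptide")$value, 3.1)

  ev2 <- make_evidence("G1", c(1, 2), pep = c(0.1, 0.2))
  expect_equal(score_protein_groups(ev2, "product_pep")$value, 0.02)
  expect_equal(score_protein_groups(ev2, "product_pep")$orientation, "lower")

  # one-hit wonder removed by the two-peptide rule
  one <- make_evidence("G1", 5, q_value = 0.004)
  expect_equal(nrow(score_protein_groups(one, "two_peptide",
                                         peptide_q_threshold = 0.01)), 0)
  two <- make_evidence("G1", c(5, 4), q_value = c(0.004, 0.008))
  expect_equal(score_protein_groups(two, "two_peptide")$value, 5)

  # Fisher on a single peptide returns that peptide's p-value
  fis <- make_evidence("G1", 1, p_value = 0.037)
  expect_equal(score_protein_groups(fis, "fisher")$value, 0.037)

  expect_error(score_protein_groups(ev, "parsimony"))
})

test_that("product of PEPs never exceeds the smallest peptide PEP", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      peps <- runif(sample(1:6, 1))
      ev <- make_evidence("G", rnorm(length(peps)), pep = peps)
      expect_lte(score_protein_groups(ev, "product_pep")$value, min(peps))
    }
  })
})

test_that("picked competition keeps the better-scoring pair member, respecting orientation", {
  sc <- data.frame(group_id = c("A", "rev_A"), is_target = c(TRUE, FALSE),
                   method = "best_peptide", value = c(0.9, 0.3),
                   orientation = "higher", n_peptides = 1L,
                   best_peptide = "X", stringsAsFactors = FALSE)
  out <- picked_competition(sc)
  expect_equal(out$group_id, "A")

  # lower-better orientation: the smaller value survives
  sc$method <- "product_pep"; sc$orientation <- "lower"
  sc$value <- c(1e-4, 1e-6)
  expect_equal(picked_competition(sc)$group_id, "rev_A")

  # exact ties remove both
  sc$value <- c(0.5, 0.5)
  expect_equal(nrow(picked_competition(sc)), 0)

  # unpaired entries survive unchanged
  sc2 <- sc; sc2$group_id <- c("A", "rev_B")
  expect_equal(nrow(picked_competition(sc2)), 2)
})

test_that("picked competition on null pairs is a fair coin", {
  withr::with_seed(21, {
    n <- 400
    sc <- data.frame(group_id = c(sprintf("T%03d", 1:n),
                                  sprintf("rev_T%03d", 1:n)),
                     is_target = rep(c(TRUE, FALSE), each = n),
                     method = "best_peptide", value = rnorm(2 * n),
                     orientation = "higher", n_peptides = 1L,
                     best_peptide = "X", stringsAsFactors = FALSE)
    out <- picked_competition(sc)
    expect_equal(nrow(out), n)
    surv_t <- sum(out$is_target)
    # ~Binomial(400, 0.5): 5 sigma band
    expect_lt(abs(surv_t - n / 2), 5 * sqrt(n / 4))
  })
})

test_that("group pairing follows the reversed member-set convention", {
  sc <- data.frame(group_id = c("A;B", "rev_A;rev_B", "rev_B;rev_C"),
                   is_target = c(TRUE, FALSE, FALSE),
                   method = "best_peptide", value = c(2, 1, 5),
                   orientation = "higher", n_peptides = 1L,
                   best_peptide = "X", stringsAsFactors = FALSE)
  out <- picked_competition(sc)
  # A;B beats its exact counterpart; rev_B;rev_C is unpaired and survives
  expect_setequal(out$group_id, c("A;B", "rev_B;rev_C"))
})

test_that("protein reports compute q-values over picked scores", {
  # all decoys eliminated: every target gets q = 1/n
  sc <- data.frame(group_id = sprintf("T%d", 1:5), is_target = TRUE,
                   method = "best_peptide", value = 5:1,
                   orientation = "higher", n_peptides = 1L,
                   best_peptide = "X", stringsAsFactors = FALSE)
  rep_ <- protein_report(sc)
  expect_equal(rep_$q_value, rep(1 / 5, 5))
  expect_equal(nrow(protein_report(sc[0, ])), 0)
  expect_equal(nrow(rep_), nrow(sc))
  # lower-better methods are orientation-normalized before ranking
  sc$method <- "fisher"; sc$orientation <- "lower"
  sc$value <- c(0.9, 0.5, 0.1, 0.2, 0.3)
  rep2 <- protein_report(sc)
  expect_equal(rep2$value[1], 0.1)
})

test_that("peptide collapse keeps the best PSM per sequence and label", {
  psms <- data.frame(spec_id = sprintf("s%d", 1:6),
                     is_target = c(T, T, T, F, F, T), scan = 1:6,
                     stringsAsFactors = FALSE)
  psms$peptide <- c("K.AAAK.R", "R.AAAK.K", "K.CCCK.R", "K.AAAK.R",
                    "K.DDDK.R", "K.AAA[16.0]K.R")
  psms$proteins <- as.list(sprintf("P%d", 1:6))
  psms$score <- c(5, 7, 3, 4, 2, 8)
  attr(psms, "feature_names") <- character(0)
  class(psms) <- c("psm_set", "data.frame")
  pt <- peptide_table(psms)
  # AAAK appears as target (best of 5, 7, 8 after mod stripping) and decoy (4)
  expect_equal(pt$score[pt$peptide == "AAAK" & pt$is_target], 8)
  expect_equal(pt$score[pt$peptide == "AAAK" & !pt$is_target], 4)
  expect_equal(nrow(pt), 4)
})
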