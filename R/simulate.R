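#' Simulation configuration for synthetic proteomes and PSM sets
#'
#' Defines the statistical structure of the synthetic data: a random
#' proteome with tryptic cleavage statistics, and per spectrum one target
#' and one decoy PSM. A target PSM is "correct" with probability
#' `prop_correct`, in which case its peptide is drawn from a present protein
#' (abundance-weighted) and its feature vector is mean-shifted by
#' `effect_size` (in units of the feature standard deviation); otherwise the
#' peptide is a random database peptide and the features are drawn from the
#' null distribution. Decoy PSMs always use the null feature distribution
#' and a peptide from the reversed database, so decoy and incorrect-target
#' features are exchangeable by construction.
#'
#' @param n_proteins Number of proteins in the proteome.
#' @param protein_length Length range (residues), sampled uniformly.
#' @param n_spectra Number of spectra (PSM pairs) to simulate.
#' @param prop_correct Fraction of spectra generated by a present peptide.
#' @param n_features Feature vector dimensionality.
#' @param effect_size Mean shift of correct-class features, recycled to
#'   `n_features`.
#' @param feature_correlation Exchangeable pairwise correlation between
#'   features, in `[0, 1)`.
#' @param present_fraction Fraction of (eligible) proteins that are present.
#' @param abundance_shape Zipf exponent for present-protein abundances
#'   (0 = uniform; default 1.5, a long-tailed abundance profile).
#' @param digest [digest_params()] used to build the peptide pools.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000L, protein_length = c(200L, 600L),
                       n_spectra = 50000L, prop_correct = 0.35,
                       n_features = 5L,
                       effect_size = c(4, 1.5, 1, 0.5, 0),
                       feature_correlation = 0.2,
                       present_fraction = 0.7, abundance_shape = 1,
                       digest = digest_params(), seed = 1L) {
  stopifnot(n_proteins >= 0, n_spectra >= 0, n_features >= 1,
            prop_correct >= 0, prop_correct <= 1,
            present_fraction >= 0, present_fraction <= 1,
            feature_correlation >= 0, feature_correlation < 1)
  effect_size <- rep_len(effect_size, n_features)
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 n_spectra = as.integer(n_spectra),
                 prop_correct = prop_correct,
                 n_features = as.integer(n_features),
                 effect_size = effect_size,
                 feature_correlation = feature_correlation,
                 present_fraction = present_fraction,
                 abundance_shape = abundance_shape,
                 digest = digest, seed = as.integer(seed)),
            class = "sim_config")
}

# residue sampling probabilities: P(K) + P(R) = 0.1 so that the expected
# tryptic fragment length is ~1 / (0.1 * (1 - P(P))) ~ 10.5 residues
aa_frequencies <- function() {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1L]]  # 18 non-K/R residues
  p <- c(rep(0.9 / 18, 18), 0.05, 0.05)
  names(p) <- c(aa, "K", "R")
  p
}

#' Simulate a random proteome
#'
#' Random amino-acid sequences over the 20-letter alphabet with K/R
#' frequency tuned so the expected tryptic peptide length is about 10
#' residues. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Protein `data.frame` (`id`, `sequence`, `is_decoy = FALSE`).
#' @export
simulate_proteome <- function(config = sim_config()) {
  n <- config$n_proteins
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      is_decoy = logical(0), stringsAsFactors = FALSE))
  }
  p <- aa_frequencies()
  withr::with_seed(config$seed, {
    lens <- sample(seq(config$protein_length[1L], config$protein_length[2L]),
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1L))
  })
  data.frame(id = sprintf("SP%05d", seq_len(n)), sequence = seqs,
             is_decoy = FALSE, stringsAsFactors = FALSE)
}

# draw n multivariate-normal rows with exchangeable correlation rho and
# given mean vector (one-factor construction, unit marginal variance)
rmvn_exch <- function(n, mean, rho) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d)
  if (rho > 0) {
    common <- stats::rnorm(n)
    z <- sqrt(1 - rho) * z + sqrt(rho) * common
  }
  sweep(z, 2L, mean, "+")
}

#' Simulate a PIN-format PSM set from a proteome
#'
#' Emits one target and one decoy PSM per spectrum (mirroring separate
#' target and decoy searches) plus a ground-truth sidecar. Present proteins
#' are a seeded subset of `present_pool` of size
#' `present_fraction * length(present_pool)`; correct target peptides are
#' drawn from present proteins with Zipf-weighted abundances, incorrect
#' target peptides uniformly from the whole target peptide pool, and decoy
#' peptides uniformly from the reversed database's peptides.
#'
#' @param proteome Target protein `data.frame`.
#' @param config A [sim_config()].
#' @param present_pool Character vector of protein ids eligible to be
#'   present (default: all of `proteome`). In the entrapment benchmark this
#'   is restricted to the sample database.
#' @param decoys Optional reversed decoy proteome (built with
#'   [reverse_proteins()] if omitted).
#' @return List with elements `psms` (a `psm_set`, see [read_pin()]),
#'   `truth` (`data.frame`: `spec_id`, `is_correct`, `source_protein`),
#'   `present` (present protein ids) and `decoys`.
#' @export
simulate_psms <- function(proteome, config = sim_config(),
                          present_pool = proteome$id, decoys = NULL) {
  if (is.null(decoys)) decoys <- reverse_proteins(proteome)
  target_sets <- digest_proteins(proteome, config$digest)
  decoy_sets <- digest_proteins(decoys, config$digest)
  target_pool <- unlist(target_sets, use.names = FALSE)
  decoy_pool <- unlist(decoy_sets, use.names = FALSE)
  if (!length(target_pool) || !length(decoy_pool)) {
    stop("proteome digests to no peptides under the configured digestion")
  }
  n <- config$n_spectra
  d <- config$n_features

  withr::with_seed(config$seed + 1L, {
    n_present <- round(config$present_fraction * length(present_pool))
    present <- sort(sample(present_pool, n_present))
    if (config$prop_correct > 0 && n_present == 0L) {
      stop("present protein set is empty while prop_correct > 0")
    }
    correct <- stats::runif(n) < config$prop_correct
    # abundance-weighted present protein per correct spectrum
    w <- if (config$abundance_shape > 0) {
      seq_len(max(n_present, 1L))^(-config$abundance_shape)
    } else {
      rep(1, max(n_present, 1L))
    }
    src <- rep(NA_character_, n)
    pep_t <- character(n)
    if (any(correct)) {
      prot <- sample(present, sum(correct), replace = TRUE, prob = w)
      pep_t[correct] <- vapply(target_sets[prot], function(s) {
        s[[sample.int(length(s), 1L)]]
      }, character(1L))
      src[correct] <- prot
    }
    if (any(!correct)) {
      pep_t[!correct] <- sample(target_pool, sum(!correct), replace = TRUE)
    }
    pep_d <- sample(decoy_pool, n, replace = TRUE)
    feat_t <- rmvn_exch(n, rep(0, d), config$feature_correlation)
    feat_t[correct, ] <- sweep(feat_t[correct, , drop = FALSE], 2L,
                               config$effect_size, "+")
    feat_d <- rmvn_exch(n, rep(0, d), config$feature_correlation)
  })

  tidx <- peptide_index(target_sets)
  didx <- peptide_index(decoy_sets)
  feat_names <- sprintf("feature%d", seq_len(d))
  build <- function(pep, feats, is_target) {
    df <- data.frame(spec_id = sprintf("spec%06d", seq_len(n)),
                     is_target = is_target, scan = seq_len(n),
                     stringsAsFactors = FALSE)
    for (j in seq_len(d)) df[[feat_names[j]]] <- feats[, j]
    df$peptide <- paste0("-.", pep, ".-")
    df$proteins <- if (is_target) unname(tidx[pep]) else unname(didx[pep])
    df
  }
  psms <- rbind(build(pep_t, feat_t, TRUE), build(pep_d, feat_d, FALSE))
  psms <- psms[order(psms$scan, !psms$is_target), , drop = FALSE]
  rownames(psms) <- NULL
  attr(psms, "feature_names") <- feat_names
  class(psms) <- c("psm_set", "data.frame")
  truth <- data.frame(spec_id = sprintf("spec%06d", seq_len(n)),
                      is_correct = correct, source_protein = src,
                      stringsAsFactors = FALSE)
  list(psms = psms, truth = truth, present = present, decoys = decoys)
}

#' Target-decoy competition on a PSM set
#'
#' `mode = "tdc"` keeps, per spectrum, only the best-scoring PSM across
#' both labels (concatenated-style competition); `mode = "rank1"` keeps the
#' best target and the best decoy per spectrum; `mode = "none"` returns the
#' input. Exact ties keep the target.
#'
#' @param psms A `psm_set`.
#' @param score Numeric vector of PSM scores (defaults to the first
#'   feature).
#' @param mode Competition mode.
#' @return The filtered `psm_set`.
#' @export
compete_psms <- function(psms, score = psms[[attr(psms, "feature_names")[1L]]],
                         mode = c("tdc", "rank1", "none")) {
  mode <- match.arg(mode)
  if (mode == "none" || !nrow(psms)) return(psms)
  key <- if (mode == "tdc") psms$spec_id else paste(psms$spec_id, psms$is_target)
  o <- order(key, -score, !psms$is_target)
  keep_first <- !duplicated(key[o])
  out <- psms[sort(o[keep_first]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_names") <- attr(psms, "feature_names")
  class(out) <- c("psm_set", "data.frame")
  out
}
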