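#' Run the sample/entrapment calibration benchmark end to end
#'
#' Builds a sample proteome and its ninefold shuffled entrapment database,
#' reverses the concatenated target database into decoys, simulates a
#' synthetic search (one target and one decoy PSM per spectrum), applies
#' PSM-level target-decoy competition, collapses to peptides, infers
#' proteins and compares the decoy-model protein q-values with the
#' observed entrapment FDR.
#'
#' @param n_sample Number of sample proteins (default 1000).
#' @param n_spectra Number of spectra (default 50000).
#' @param method Protein inference method (default `"best_peptide"`).
#' @param grouping `"theoretical"` (unique peptides), `"observed"` (shared
#'   peptides retained), or `"both"` to evaluate the two modes on the same
#'   simulated search (returns a named list of runs).
#' @param peptide_q_threshold Peptide threshold for observed-mode grouping
#'   (default 0.10).
#' @param multiplier,shared_rate Entrapment construction; see
#'   [entrapment_config()].
#' @param sim Optional [sim_config()] template; `n_proteins`, `n_spectra`
#'   and `seed` are overridden.
#' @param seed Integer seed for the whole run.
#' @return List of class `entrapment_run`: `curve`
#'   ([calibration_curve()] over accepted targets), `report`, `db`,
#'   `truth`, `n_accepted_01` and `entrapment_fdr_01` (at reported decoy
#'   q-value 0.01).
#' @export
run_entrapment_benchmark <- function(n_sample = 1000L, n_spectra = 50000L,
                                     method = "best_peptide",
                                     grouping = c("theoretical", "observed",
                                                  "both"),
                                     peptide_q_threshold = 0.10,
                                     multiplier = 9L, shared_rate = 0.04,
                                     sim = sim_config(), seed = 1L) {
  grouping <- match.arg(grouping)
  sim$n_proteins <- as.integer(n_sample)
  sim$n_spectra <- as.integer(n_spectra)
  sim$seed <- as.integer(seed)
  sample_db <- simulate_proteome(sim)
  db <- build_entrapment_db(sample_db,
                            entrapment_config(multiplier = multiplier,
                                              shared_rate = shared_rate,
                                              digest = sim$digest,
                                              seed = seed))
  targets <- rbind(db$sample, db$entrapment)
  decoys <- reverse_proteins(targets)
  sim_out <- simulate_psms(targets, sim, present_pool = db$sample$id,
                           decoys = decoys)
  psms <- compete_psms(sim_out$psms, mode = "tdc")
  psms$score <- psms[[attr(psms, "feature_names")[1L]]]
  all_prot <- rbind(targets, decoys)
  sets <- digest_proteins(all_prot, sim$digest)
  one_mode <- function(mode) {
    inf <- infer_proteins(psms, all_prot, method = method,
                          grouping = mode, params = sim$digest,
                          peptide_q_threshold = if (mode == "observed")
                            peptide_q_threshold else 0.01,
                          peptide_sets = sets)
    rep_t <- inf$report[inf$report$is_target, , drop = FALSE]
    # a group is an entrapment entity only if every member is entrapment
    is_entr <- vapply(strsplit(rep_t$group_id, ";", fixed = TRUE),
                      function(m) all(grepl("_entrap", m)), logical(1L))
    curve <- calibration_curve(rep_t$q_value, is_entr)
    at01 <- rep_t$q_value <= 0.01
    structure(list(curve = curve, report = inf$report, db = db,
                   truth = sim_out$truth,
                   n_accepted_01 = sum(at01),
                   entrapment_fdr_01 = if (any(at01))
                     mean(is_entr[at01]) else NA_real_,
                   grouping = mode, method = method, seed = seed),
              class = "entrapment_run")
  }
  if (grouping == "both") {
    list(theoretical = one_mode("theoretical"),
         observed = one_mode("observed"))
  } else {
    one_mode(grouping)
  }
}

#' @export
print.entrapment_run <- function(x, ...) {
  cat(sprintf("entrapment benchmark run (%s grouping, %s): %d target groups at q <= 0.01, entrapment FDR %.4f\n",
              x$grouping, x$method, x$n_accepted_01, x$entrapment_fdr_01))
  print(x$curve)
  invisible(x)
}

#' Compare the four protein inference methods on one synthetic data set
#'
#' Simulates a search, applies PSM competition, and counts accepted target
#' protein groups at a protein-level FDR threshold for each inference
#' method under unique-peptide (theoretical) grouping with picked FDR.
#'
#' @param n_proteins,n_spectra Proteome and spectrum counts.
#' @param q_threshold Protein-level q-value threshold (default 0.01).
#' @param sim Optional [sim_config()] template.
#' @param seed Integer seed.
#' @return Named integer vector of accepted target group counts per
#'   method.
#' @export
compare_inference_methods <- function(n_proteins = 2000L,
                                      n_spectra = 100000L,
                                      q_threshold = 0.01,
                                      sim = sim_config(), seed = 1L) {
  sim$n_proteins <- as.integer(n_proteins)
  sim$n_spectra <- as.integer(n_spectra)
  sim$seed <- as.integer(seed)
  proteome <- simulate_proteome(sim)
  decoys <- reverse_proteins(proteome)
  sim_out <- simulate_psms(proteome, sim, decoys = decoys)
  psms <- compete_psms(sim_out$psms, mode = "tdc")
  psms$score <- psms[[attr(psms, "feature_names")[1L]]]
  all_prot <- rbind(proteome, decoys)
  # shared setup across methods
  peptides <- peptide_table(psms)
  sets <- digest_proteins(all_prot, sim$digest)
  groups <- group_by_theoretical_peptides(all_prot, sim$digest,
                                          peptide_sets = sets)
  gt <- groups[!groups$is_decoy, , drop = FALSE]
  gd <- groups[groups$is_decoy, , drop = FALSE]
  class(gt) <- class(gd) <- c("protein_groups", "data.frame")
  evidence <- build_evidence(peptides, gt, gd, mode = "unique")
  methods <- c("best_peptide", "two_peptide", "product_pep", "fisher")
  counts <- vapply(methods, function(m) {
    sc <- score_protein_groups(evidence, method = m,
                               peptide_q_threshold = 0.01)
    rep_ <- protein_report(picked_competition(sc))
    sum(rep_$is_target & rep_$q_value <= q_threshold)
  }, integer(1L))
  counts
}

#' Subset-training stability of the rescoring SVM
#'
#' For each seed, simulates a PSM set, trains the rescoring SVM on the full
#' data and on a random spectrum-preserving subset, and reports the ratio
#' of targets significant at `q <= 0.01` (subset / full).
#'
#' @param n_spectra Number of spectra (PSM pairs).
#' @param subset_size Subset size in PSMs.
#' @param seeds Integer vector of seeds.
#' @param sim Optional [sim_config()] template.
#' @param config Optional [train_config()] template.
#' @return `data.frame` with `seed`, `n_full`, `n_subset`, `ratio`.
#' @export
subset_stability <- function(n_spectra = 100000L, subset_size = 20000L,
                             seeds = 1:10, sim = sim_config(),
                             config = train_config()) {
  sim$n_proteins <- min(sim$n_proteins, 1000L)
  res <- lapply(seeds, function(s) {
    sim$n_spectra <- as.integer(n_spectra)
    sim$seed <- as.integer(s)
    proteome <- simulate_proteome(sim)
    sim_out <- simulate_psms(proteome, sim)
    config$seed <- as.integer(s)
    config$subset_size <- NULL
    full <- rescore(sim_out$psms, config)
    config$subset_size <- as.integer(subset_size)
    sub <- rescore(sim_out$psms, config)
    n_full <- sum(full$psms$is_target & full$psms$q_value <= 0.01)
    n_sub <- sum(sub$psms$is_target & sub$psms$q_value <= 0.01)
    data.frame(seed = s, n_full = n_full, n_subset = n_sub,
               ratio = n_sub / n_full)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
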