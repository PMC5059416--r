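#' Collapse PSMs to peptide-level evidence
#'
#' Keeps the best-scoring PSM per distinct (stripped) peptide sequence per
#' label, then computes peptide-level q-values, PEPs and empirical decoy
#' p-values.
#'
#' @param psms A `psm_set` carrying a `score` column (or supply `score`).
#' @param score Numeric PSM scores (defaults to `psms$score`).
#' @return `data.frame` with columns `peptide` (bare sequence),
#'   `is_target`, `score`, `q_value`, `pep`, `p_value`, sorted by
#'   descending score.
#' @export
peptide_table <- function(psms, score = psms$score) {
  stopifnot(!is.null(score))
  bare <- strip_peptide(psms$peptide)
  key <- paste(bare, psms$is_target)
  o <- order(key, -score)
  keep <- o[!duplicated(key[o])]
  tab <- data.frame(id = bare[keep], score = score[keep],
                    is_target = psms$is_target[keep],
                    stringsAsFactors = FALSE)
  tab <- confidence_table(tab, p_values = any(!tab$is_target))
  names(tab)[names(tab) == "id"] <- "peptide"
  tab
}

#' Score protein groups from peptide-level evidence
#'
#' Four inference methods:
#' \describe{
#'   \item{`best_peptide`}{maximum peptide score in the group
#'     (higher-better).}
#'   \item{`two_peptide`}{maximum peptide score, but groups with fewer than
#'     two distinct peptides at `q <= peptide_q_threshold` are removed
#'     (the classical guard against one-hit wonders).}
#'   \item{`product_pep`}{product of the peptide-level PEPs over all the
#'     group's inferred peptides (lower-better, unscaled by length).}
#'   \item{`fisher`}{Fisher's combination of the group's peptide p-values
#'     (lower-better; accounts for the number of peptides combined).}
#' }
#'
#' @param evidence `data.frame` with columns `group_id`, `peptide`,
#'   `score`, `q_value`, `pep`, `p_value`, `is_target` (one row per
#'   distinct peptide per group).
#' @param method One of `"best_peptide"`, `"two_peptide"`,
#'   `"product_pep"`, `"fisher"`.
#' @param peptide_q_threshold Peptide q-value threshold used by the
#'   two-peptide count (default 0.01).
#' @return `data.frame` with `group_id`, `is_target`, `method`, `value`,
#'   `orientation` (`"higher"`/`"lower"`), `n_peptides`, `best_peptide`.
#'   Groups with no evidence are absent.
#' @export
score_protein_groups <- function(evidence,
                                 method = c("best_peptide", "two_peptide",
                                            "product_pep", "fisher"),
                                 peptide_q_threshold = 0.01) {
  method <- match.arg(method)
  if (!nrow(evidence)) {
    return(data.frame(group_id = character(0), is_target = logical(0),
                      method = character(0), value = numeric(0),
                      orientation = character(0), n_peptides = integer(0),
                      best_peptide = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(evidence$group_id, evidence$is_target)
  parts <- split(seq_len(nrow(evidence)), key)
  first <- vapply(parts, `[[`, integer(1L), 1L)
  value <- switch(method,
    best_peptide = vapply(parts, function(i) max(evidence$score[i]),
                          numeric(1L)),
    two_peptide = vapply(parts, function(i) {
      if (sum(evidence$q_value[i] <= peptide_q_threshold) >= 2L)
        max(evidence$score[i]) else NA_real_
    }, numeric(1L)),
    product_pep = vapply(parts, function(i) prod(evidence$pep[i]),
                         numeric(1L)),
    fisher = vapply(parts, function(i) fisher_combine(evidence$p_value[i]),
                    numeric(1L)))
  best_idx <- vapply(parts, function(i) i[which.max(evidence$score[i])],
                     integer(1L))
  out <- data.frame(group_id = evidence$group_id[first],
                    is_target = evidence$is_target[first],
                    method = method, value = unname(value),
                    orientation = if (method %in% c("best_peptide",
                                                    "two_peptide"))
                      "higher" else "lower",
                    n_peptides = lengths(parts),
                    best_peptide = evidence$peptide[best_idx],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$value), , drop = FALSE]   # two-peptide removals
  rownames(out) <- NULL
  out
}

#' Picked target-decoy competition at the protein-group level
#'
#' A target group is paired with the decoy group whose member set is
#' exactly the prefixed (reversed) counterparts of the target members.
#' Within each pair only the better-scoring member survives, respecting the
#' method's orientation; exact ties remove both. Unpaired groups survive
#' unchanged.
#'
#' @param scores Output of [score_protein_groups()] containing both
#'   targets and decoys.
#' @param decoy_prefix Accession prefix of decoy proteins (default
#'   `"rev_"`).
#' @return The surviving subset of `scores`.
#' @export
picked_competition <- function(scores, decoy_prefix = "rev_") {
  t_rows <- which(scores$is_target)
  d_rows <- which(!scores$is_target)
  # decoy counterpart id of each target group
  counterpart <- vapply(strsplit(scores$group_id[t_rows], ";", fixed = TRUE),
                        function(m) paste(sort(paste0(decoy_prefix, m)),
                                          collapse = ";"),
                        character(1L))
  if (any(counterpart %in% scores$group_id[t_rows])) {
    stop("a group id appears on both sides of the target/decoy pairing")
  }
  match_d <- match(counterpart, scores$group_id[d_rows])
  paired <- which(!is.na(match_d))
  drop <- logical(nrow(scores))
  for (i in paired) {
    ti <- t_rows[i]
    di <- d_rows[match_d[i]]
    vt <- scores$value[ti]
    vd <- scores$value[di]
    higher <- scores$orientation[ti] == "higher"
    if (vt == vd) {
      drop[c(ti, di)] <- TRUE
    } else if ((higher && vt > vd) || (!higher && vt < vd)) {
      drop[di] <- TRUE
    } else {
      drop[ti] <- TRUE
    }
  }
  out <- scores[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein-level confidence report
#'
#' Normalizes the method's orientation so that higher is better, estimates
#' protein-level q-values by target-decoy competition and returns the
#' report sorted by descending score. Apply [picked_competition()] first.
#'
#' @param picked Output of [picked_competition()].
#' @return `data.frame` with `group_id`, `is_target`, `method`, `score`
#'   (orientation-normalized), `value` (the method's raw value),
#'   `q_value`, `n_peptides`, `best_peptide`.
#' @export
protein_report <- function(picked) {
  if (!nrow(picked)) {
    return(data.frame(group_id = character(0), is_target = logical(0),
                      method = character(0), score = numeric(0),
                      value = numeric(0), q_value = numeric(0),
                      n_peptides = integer(0), best_peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  score <- ifelse(picked$orientation == "higher", picked$value,
                  -picked$value)
  q <- td_qvalues(score, picked$is_target)
  out <- data.frame(group_id = picked$group_id,
                    is_target = picked$is_target, method = picked$method,
                    score = score, value = picked$value, q_value = q,
                    n_peptides = picked$n_peptides,
                    best_peptide = picked$best_peptide,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# build group-level peptide evidence from a peptide table.
# unique mode: peptides mapped to exactly one group of their label.
# observed mode: every (group, contained peptide) pair is evidence.
build_evidence <- function(peptides, groups_target, groups_decoy,
                           mode = c("unique", "observed")) {
  mode <- match.arg(mode)
  one_label <- function(pt, groups) {
    if (is.null(groups) || !nrow(groups) || !nrow(pt)) {
      return(cbind(pt[0, , drop = FALSE],
                   data.frame(group_id = character(0))))
    }
    pepmap <- assign_unique_peptides(groups)
    if (mode == "unique") {
      m <- pepmap[pepmap$unique, c("peptide", "group_id")]
      hit <- match(pt$peptide, m$peptide)
      out <- pt[!is.na(hit), , drop = FALSE]
      out$group_id <- m$group_id[hit[!is.na(hit)]]
    } else {
      hit <- match(pt$peptide, pepmap$peptide)
      keep <- which(!is.na(hit))
      reps <- pepmap$n_groups[hit[keep]]
      out <- pt[rep(keep, reps), , drop = FALSE]
      out$group_id <- unlist(pepmap$group_ids[hit[keep]], use.names = FALSE)
    }
    out
  }
  ev <- rbind(one_label(peptides[peptides$is_target, , drop = FALSE],
                        groups_target),
              one_label(peptides[!peptides$is_target, , drop = FALSE],
                        groups_decoy))
  rownames(ev) <- NULL
  ev
}

#' Protein inference from a scored PSM set
#'
#' Runs the full protein-level pipeline: best-PSM collapse to peptides,
#' peptide-level confidence estimates, protein grouping, group scoring by
#' the chosen method, picked target-decoy competition, and protein-level
#' q-values.
#'
#' In `grouping = "theoretical"` (unique-peptide) mode, proteins are
#' grouped by their theoretical digests before any data is observed and
#' only group-unique peptides are used. In `grouping = "observed"` mode,
#' proteins are grouped by their sets of inferred peptides at
#' `peptide_q_threshold` and shared peptides are retained (the poorly
#' calibrated mode, kept for benchmarking).
#'
#' @param psms A `psm_set` with a `score` column.
#' @param proteins Target+decoy protein `data.frame` (see
#'   [read_fasta()]).
#' @param method Inference method; see [score_protein_groups()].
#' @param grouping `"theoretical"` or `"observed"`.
#' @param params [digest_params()] for the theoretical digest.
#' @param peptide_q_threshold Peptide q-value threshold (two-peptide
#'   counting; observed-mode grouping). Default 0.01 for
#'   `"theoretical"`; a common choice for `"observed"` is 0.10.
#' @param decoy_prefix Decoy accession prefix.
#' @param peptide_sets Optional precomputed digest (named list of peptide
#'   vectors per protein id).
#' @return List with `report` (see [protein_report()]), `peptides`,
#'   `groups` and `evidence`.
#' @export
infer_proteins <- function(psms, proteins,
                           method = "best_peptide",
                           grouping = c("theoretical", "observed"),
                           params = digest_params(),
                           peptide_q_threshold = 0.01,
                           decoy_prefix = "rev_", peptide_sets = NULL) {
  grouping <- match.arg(grouping)
  peptides <- peptide_table(psms)
  sets <- if (is.null(peptide_sets)) digest_proteins(proteins, params) else
    peptide_sets
  if (grouping == "theoretical") {
    groups <- group_by_theoretical_peptides(proteins, params,
                                            peptide_sets = sets)
    gt <- groups[!groups$is_decoy, , drop = FALSE]
    gd <- groups[groups$is_decoy, , drop = FALSE]
  } else {
    inferred <- peptides$peptide[peptides$q_value <= peptide_q_threshold]
    observed_sets <- lapply(sets, intersect, y = inferred)
    groups <- group_by_observed_peptides(observed_sets,
                                         is_decoy = proteins$is_decoy)
    gt <- groups[!groups$is_decoy, , drop = FALSE]
    gd <- groups[groups$is_decoy, , drop = FALSE]
    peptides <- peptides[peptides$q_value <= peptide_q_threshold, ,
                         drop = FALSE]
  }
  class(gt) <- class(gd) <- c("protein_groups", "data.frame")
  evidence <- build_evidence(peptides, gt, gd,
                             mode = if (grouping == "theoretical")
                               "unique" else "observed")
  scores <- score_protein_groups(evidence, method = method,
                                 peptide_q_threshold = peptide_q_threshold)
  picked <- picked_competition(scores, decoy_prefix = decoy_prefix)
  list(report = protein_report(picked), peptides = peptides,
       groups = groups, evidence = evidence)
}

#' Write a protein report to TSV
#'
#' Columns: `group_id`, `members`, `label`, `method`, `score`, `q_value`,
#' `n_peptides`, `best_peptide`.
#'
#' @param report Output of [protein_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_tsv <- function(report, path) {
  # group ids are the semicolon-joined member accessions
  out <- data.frame(group_id = report$group_id,
                    members = report$group_id,
                    label = ifelse(report$is_target, "target", "decoy"),
                    method = report$method, score = report$score,
                    q_value = report$q_value,
                    n_peptides = report$n_peptides,
                    best_peptide = report$best_peptide,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
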