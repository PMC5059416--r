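#' Group proteins by their theoretical peptide sets
#'
#' Proteins with identical theoretical (in-silico digested) peptide sets are
#' merged, and a protein whose peptide set is a strict subset of exactly one
#' maximal peptide set is merged into that group. A protein whose set is a
#' strict subset of two or more non-nested maximal sets is left as its own
#' group (deterministic, conservative handling of ambiguity). Targets and
#' decoys are grouped independently and never share a group. Proteins that
#' digest to an empty peptide set are placed in singleton groups and flagged:
#' they can never be identified.
#'
#' @param proteins Protein `data.frame` with `id`, `sequence`, `is_decoy`.
#' @param params [digest_params()] used for the theoretical digest.
#' @param peptide_sets Optional precomputed named list of peptide vectors
#'   (one per protein id), bypassing the digest.
#' @return A `data.frame` of class `protein_groups` with columns `group_id`
#'   (member ids sorted bytewise, joined by `";"`), `members` (list),
#'   `peptides` (list), `is_decoy`, `n_members`, `n_peptides`,
#'   `empty_digest`.
#' @export
group_by_theoretical_peptides <- function(proteins, params = digest_params(),
                                          peptide_sets = NULL) {
  if (anyDuplicated(proteins$id)) stop("protein ids must be unique")
  if (is.null(peptide_sets)) peptide_sets <- digest_proteins(proteins, params)
  sets <- peptide_sets[proteins$id]
  out <- list()
  for (dec in unique(proteins$is_decoy)) {
    ids <- proteins$id[proteins$is_decoy == dec]
    g <- group_peptide_sets(sets[ids])
    if (nrow(g)) g$is_decoy <- dec
    out[[length(out) + 1L]] <- g
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(group_id = character(0), is_decoy = logical(0))
    res$members <- list(); res$peptides <- list()
    res$n_members <- integer(0); res$n_peptides <- integer(0)
    res$empty_digest <- logical(0)
  }
  res <- res[order(res$group_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("protein_groups", "data.frame")
  res
}

# core grouping over a named list of peptide-string sets (one label at a time)
group_peptide_sets <- function(sets) {
  ids <- names(sets)
  empty <- lengths(sets) == 0L
  # integer-code the peptides once for fast set algebra
  flat <- unlist(sets, use.names = FALSE)
  all_pep <- unique(flat)
  codes <- match(flat, all_pep)
  isets <- split(codes, factor(rep(seq_along(sets), lengths(sets)),
                               levels = seq_along(sets)))
  isets <- unname(lapply(isets, sort.int))

  # 1) merge identical sets
  key <- vapply(isets, paste, character(1L), collapse = ",")
  key[empty] <- paste0("<empty>", ids[empty])  # empty digests stay singletons
  grp_of <- split(ids, key)                    # key -> member ids
  ukey <- names(grp_of)
  rep_set <- isets[match(vapply(grp_of, `[[`, character(1L), 1L), ids)]
  ng <- length(ukey)

  # 2) subset merging into uniquely-containing maximal sets
  # inverted index over current groups (positional, one slot per peptide)
  sizes <- lengths(rep_set)
  owner <- rep(seq_len(ng), sizes)
  flat_g <- unlist(rep_set, use.names = FALSE)
  bypep <- vector("list", length(all_pep))
  if (length(flat_g)) {
    o <- order(flat_g)
    present <- unique(flat_g[o])
    bypep[present] <- split(owner[o], flat_g[o])
  }
  npep_owner <- lengths(bypep)
  # rarest peptide per group bounds the candidate supersets
  strict_sup <- vector("list", ng)
  for (g in seq_len(ng)) {
    s <- rep_set[[g]]
    if (!length(s)) next
    rare <- bypep[[s[which.min(npep_owner[s])]]]
    cand <- rare[sizes[rare] > sizes[g]]
    if (!length(cand)) next
    hit <- cand[vapply(cand, function(h) all(s %in% rep_set[[h]]), logical(1L))]
    strict_sup[[g]] <- hit
  }
  has_sup <- lengths(strict_sup) > 0L
  maximal <- which(!has_sup)
  merged_into <- rep(NA_integer_, ng)
  for (g in which(has_sup)) {
    msup <- intersect(strict_sup[[g]], maximal)
    if (length(msup) == 1L) merged_into[g] <- msup
  }
  dest <- ifelse(is.na(merged_into), seq_len(ng), merged_into)

  members <- lapply(split(seq_len(ng), dest),
                    function(gs) sort(unlist(grp_of[gs], use.names = FALSE)))
  keep <- as.integer(names(members))
  peptides <- lapply(keep, function(g) sort(all_pep[rep_set[[g]]]))
  df <- data.frame(group_id = vapply(members, paste, character(1L),
                                     collapse = ";"),
                   stringsAsFactors = FALSE)
  df$members <- unname(members)
  df$peptides <- peptides
  df$n_members <- lengths(members)
  df$n_peptides <- lengths(peptides)
  df$empty_digest <- df$n_peptides == 0L
  df
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("%d protein group(s): %d protein(s), %d target group(s), %d decoy group(s)\n",
              nrow(x), sum(x$n_members), sum(!x$is_decoy), sum(x$is_decoy)))
  if (any(x$empty_digest)) {
    cat(sprintf("  %d group(s) with an empty theoretical digest (unidentifiable)\n",
                sum(x$empty_digest)))
  }
  invisible(x)
}

#' Map peptides to the protein groups that contain them
#'
#' Builds the peptide -> group map over a set of groups (one label at a
#' time; call separately for targets and decoys). Downstream inference in
#' unique-peptide mode uses only peptides with exactly one owning group.
#'
#' @param groups A `protein_groups` table (typically one label).
#' @return `data.frame` with columns `peptide`, `group_ids` (list),
#'   `n_groups`, `unique` (`TRUE` iff exactly one group), and `group_id`
#'   (the owner when unique, otherwise `NA`).
#' @export
assign_unique_peptides <- function(groups) {
  sets <- groups$peptides
  names(sets) <- groups$group_id
  idx <- peptide_index(sets)
  if (!length(idx)) {
    out <- data.frame(peptide = character(0), n_groups = integer(0),
                      unique = logical(0), group_id = character(0),
                      stringsAsFactors = FALSE)
    out$group_ids <- list()
    return(out)
  }
  out <- data.frame(peptide = names(idx), n_groups = lengths(idx),
                    stringsAsFactors = FALSE)
  out$group_ids <- unname(idx)
  out$unique <- out$n_groups == 1L
  out$group_id <- ifelse(out$unique,
                         vapply(idx, `[[`, character(1L), 1L), NA_character_)
  rownames(out) <- NULL
  out
}

#' Group proteins by their observed (inferred) peptide sets
#'
#' The grouping used when shared peptides are retained: proteins with the
#' same set of inferred peptides (those passing a peptide-level q-value
#' threshold) are merged, and proteins whose inferred set is a strict subset
#' of exactly one maximal inferred set are added to that group. Proteins
#' with no inferred peptides are dropped.
#'
#' @param observed_sets Named list: protein id -> character vector of
#'   inferred peptides.
#' @param is_decoy Logical vector parallel to `observed_sets` (default all
#'   targets).
#' @return A `protein_groups` table (see
#'   [group_by_theoretical_peptides()]).
#' @export
group_by_observed_peptides <- function(observed_sets,
                                       is_decoy = rep(FALSE, length(observed_sets))) {
  keep <- lengths(observed_sets) > 0L
  observed_sets <- observed_sets[keep]
  is_decoy <- is_decoy[keep]
  out <- list()
  for (dec in unique(is_decoy)) {
    g <- group_peptide_sets(observed_sets[is_decoy == dec])
    if (nrow(g)) g$is_decoy <- dec
    out[[length(out) + 1L]] <- g
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- group_by_theoretical_peptides(
      data.frame(id = character(0), sequence = character(0),
                 is_decoy = logical(0)), peptide_sets = list())
    return(res)
  }
  res <- res[order(res$group_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("protein_groups", "data.frame")
  res
}

#' Summarize the gain in identifiable entities from protein grouping
#'
#' Counts proteins having at least one protein-specific peptide and protein
#' groups having at least one group-specific peptide. Grouping converts
#' peptides shared only among the merged proteins into group-specific
#' evidence, so the group count is never smaller.
#'
#' @param proteins Protein `data.frame` (targets).
#' @param params [digest_params()].
#' @return Named list: `n_proteins`, `n_peptides`,
#'   `n_proteins_with_specific_peptides`, `n_groups`,
#'   `n_groups_with_specific_peptides`.
#' @export
grouping_summary <- function(proteins, params = digest_params()) {
  sets <- digest_proteins(proteins, params)
  idx <- peptide_index(sets)
  prot_specific <- unlist(idx[lengths(idx) == 1L], use.names = FALSE)
  groups <- group_by_theoretical_peptides(proteins, params,
                                          peptide_sets = sets)
  pepmap <- assign_unique_peptides(groups)
  grp_specific <- pepmap$group_id[pepmap$unique]
  list(n_proteins = nrow(proteins),
       n_peptides = length(idx),
       n_proteins_with_specific_peptides = length(unique(prot_specific)),
       n_groups = nrow(groups),
       n_groups_with_specific_peptides = length(unique(grp_specific)))
}

#' Write a protein grouping table to TSV
#'
#' Columns: `group_id`, `members` (semicolon-joined),
#' `n_theoretical_peptides`, `n_group_unique_peptides`.
#'
#' @param groups `protein_groups` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grouping_tsv <- function(groups, path) {
  pepmap <- assign_unique_peptides(groups)
  uniq <- table(pepmap$group_id[pepmap$unique])
  out <- data.frame(group_id = groups$group_id,
                    members = vapply(groups$members, paste, character(1L),
                                     collapse = ";"),
                    n_theoretical_peptides = groups$n_peptides,
                    n_group_unique_peptides =
                      as.integer(uniq[groups$group_id]),
                    stringsAsFactors = FALSE)
  out$n_group_unique_peptides[is.na(out$n_group_unique_peptides)] <- 0L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
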