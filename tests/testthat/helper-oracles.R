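# Independent brute-force oracles used to validate the fast implementations.

# Digestion oracle: enumerate every substring whose boundaries are valid cut
# positions (or termini) and which spans at most `mc` internal cut sites.
oracle_digest <- function(sequence, params) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sites <- integer(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (chars[i] %in% params$cleave_after &&
        !(params$suppress_proline && chars[i + 1L] == "P")) {
      sites <- c(sites, i)
    }
  }
  bounds <- c(0L, sites, n)
  peps <- character(0)
  for (a in bounds) {
    for (b in bounds) {
      if (b <= a) next
      internal <- sum(sites > a & sites < b)
      len <- b - a
      if (internal <= params$missed_cleavages &&
          len >= params$min_length && len <= params$max_length) {
        peps <- c(peps, substr(sequence, a + 1L, b))
      }
    }
  }
  sort(unique(peps))
}

# q-value oracle: evaluate (1 + #decoys >= t) / #targets >= t at every
# entity's score threshold, then take for each entity the minimum over all
# thresholds at or below its score.
oracle_qvalues <- function(score, is_target) {
  vapply(seq_along(score), function(i) {
    fdrs <- vapply(unique(score[score <= score[i]]), function(t) {
      nt <- sum(is_target & score >= t)
      if (nt == 0L) return(Inf)
      (1 + sum(!is_target & score >= t)) / nt
    }, numeric(1L))
    min(1, min(fdrs))
  }, numeric(1L))
}

# grouping oracle: exhaustive pairwise subset relations, identical-set merge
# plus unique-maximal-superset merge, no indexing tricks
oracle_group <- function(sets) {
  ids <- names(sets)
  n <- length(sets)
  same <- function(a, b) setequal(sets[[a]], sets[[b]])
  strict_subset <- function(a, b) {
    all(sets[[a]] %in% sets[[b]]) && !setequal(sets[[a]], sets[[b]])
  }
  rep_id <- ids
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (same(ids[i], ids[j])) rep_id[i] <- rep_id[j]
    }
  }
  reps <- unique(rep_id)
  is_max <- vapply(reps, function(a) {
    !any(vapply(reps, function(b) strict_subset(a, b), logical(1L)))
  }, logical(1L))
  dest <- vapply(reps, function(a) {
    sups <- reps[is_max & vapply(reps, function(b) strict_subset(a, b),
                                 logical(1L))]
    if (length(sups) == 1L) sups else a
  }, character(1L))
  members <- lapply(unique(dest), function(d) {
    sort(ids[rep_id %in% reps[dest == d]])
  })
  sort(vapply(members, paste, character(1L), collapse = ";"))
}

random_sequence <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

small_proteome <- function(n = 20, len = 60, seed = 1) {
  withr::with_seed(seed, {
    data.frame(id = sprintf("P%03d", seq_len(n)),
               sequence = vapply(seq_len(n), function(i) random_sequence(len),
                                 character(1L)),
               is_decoy = FALSE, stringsAsFactors = FALSE)
  })
}
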