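#' Entrapment benchmark configuration
#'
#' @param multiplier Entrapment database size as a multiple of the sample
#'   database (default 9).
#' @param shared_rate Fraction of distinct sample peptides kept unshuffled
#'   (verbatim) in the entrapment database, in `[0, 1)` (default 0.04).
#' @param digest [digest_params()] defining the peptides being shuffled.
#' @param seed Integer seed.
#' @return Object of class `entrapment_config`.
#' @export
entrapment_config <- function(multiplier = 9L, shared_rate = 0.04,
                              digest = digest_params(), seed = 1L) {
  multiplier <- as.integer(multiplier)
  if (multiplier < 1L) stop("multiplier must be >= 1")
  if (shared_rate < 0 || shared_rate >= 1) stop("shared_rate must be in [0, 1)")
  structure(list(multiplier = multiplier, shared_rate = shared_rate,
                 digest = digest, seed = as.integer(seed)),
            class = "entrapment_config")
}

# permute the residues of one fragment, holding every K, R and P in place.
# Fixing K/R/P preserves all tryptic cleavage sites and their proline
# suppression, so entrapment proteins re-digest on exactly the source
# boundaries.
shuffle_fragment <- function(chars, movable) {
  if (length(movable) < 2L) return(paste(chars, collapse = ""))
  chars[movable] <- chars[sample(movable)]
  paste(chars, collapse = "")
}

#' Build a sample/entrapment benchmark database
#'
#' For each of `multiplier` copies of every sample protein, the protein is
#' digested and each fragment's residues are shuffled (K, R and P are held
#' in place so tryptic boundaries survive re-digestion), except that a
#' globally selected set of `floor(shared_rate * n_distinct_peptides)`
#' sample peptides is kept verbatim in every copy, creating controlled
#' shared peptides between sample and entrapment. A shuffle that reproduces
#' the original fragment or collides with any distinct sample peptide is
#' redrawn up to 10 times, then accepted and flagged. Shuffles are
#' independent per copy.
#'
#' @param sample Sample protein `data.frame` (targets).
#' @param config An [entrapment_config()].
#' @return List of class `benchmark_db`: `sample`, `entrapment` (protein
#'   `data.frame`, ids `<source>_entrap<k>`), `shared_peptides`, `config`,
#'   and `n_flagged` (fragments accepted after 10 failed redraws).
#' @export
build_entrapment_db <- function(sample, config = entrapment_config()) {
  if (!nrow(sample)) stop("sample database is empty")
  params <- config$digest
  frag_list <- lapply(sample$sequence, base_fragments, params = params)
  sample_peps <- sort(unique(unlist(
    lapply(sample$sequence, digest, params = params), use.names = FALSE)))
  n_shared <- floor(config$shared_rate * length(sample_peps))

  withr::with_seed(config$seed, {
    shared <- if (n_shared > 0L) sort(sample(sample_peps, n_shared)) else character(0)
    frag_chars <- lapply(frag_list, strsplit, split = "", fixed = TRUE)
    movable <- lapply(frag_chars, function(pr) {
      lapply(pr, function(ch) which(!(ch %in% c("K", "R", "P"))))
    })
    is_shared <- lapply(frag_list, function(fr) fr %in% shared)
    n_flagged <- 0L
    entr <- vector("list", config$multiplier)
    for (copy in seq_len(config$multiplier)) {
      seqs <- vapply(seq_along(frag_list), function(i) {
        fr <- frag_list[[i]]
        out <- fr
        todo <- which(!is_shared[[i]])
        fixable <- vapply(todo, function(j) {
          ch <- frag_chars[[i]][[j]][movable[[i]][[j]]]
          length(ch) >= 2L && length(unique(ch)) > 1L
        }, logical(1L))
        for (attempt in seq_len(10L)) {
          if (!length(todo)) break
          out[todo] <- vapply(todo, function(j) {
            shuffle_fragment(frag_chars[[i]][[j]], movable[[i]][[j]])
          }, character(1L))
          bad <- out[todo] == fr[todo] | out[todo] %in% sample_peps
          if (attempt == 1L) {
            # fragments that can never change (degenerate residue content)
            n_flagged <<- n_flagged + sum(bad & !fixable)
          }
          keep <- bad & fixable
          todo <- todo[keep]
          fixable <- fixable[keep]
        }
        n_flagged <<- n_flagged + length(todo)
        paste(out, collapse = "")
      }, character(1L))
      entr[[copy]] <- data.frame(
        id = paste0(sample$id, "_entrap", copy), sequence = seqs,
        is_decoy = FALSE, stringsAsFactors = FALSE)
    }
  })
  structure(list(sample = sample, entrapment = do.call(rbind, entr),
                 shared_peptides = shared, config = config,
                 n_flagged = n_flagged),
            class = "benchmark_db")
}

#' @export
print.benchmark_db <- function(x, ...) {
  cat(sprintf("sample/entrapment benchmark database: %d sample, %d entrapment proteins (x%d), %d shared peptides\n",
              nrow(x$sample), nrow(x$entrapment), x$config$multiplier,
              length(x$shared_peptides)))
  invisible(x)
}

#' Expected PSM-level undercount of the entrapment FDR
#'
#' Incorrect matches distribute between entrapment and sample databases in
#' proportion `multiplier : 1`, so counting only entrapment matches as
#' false positives misses `1/multiplier` of them relative to the counted
#' amount: the entrapment FDR underestimates the true false-positive count
#' by `1/multiplier` (about 11% for the default ninefold database).
#'
#' @param multiplier Entrapment/sample size ratio.
#' @return Expected relative undercount (a fraction).
#' @export
entrapment_undercount <- function(multiplier = 9L) {
  stopifnot(multiplier >= 1)
  1 / multiplier
}

#' Entrapment FDR along a ranked target list
#'
#' Given accepted target entities in descending score order, returns the
#' running fraction of entrapment entities: `#entrapment / (#entrapment +
#' #sample)` at each threshold. A protein group counts as entrapment only
#' if all its members are entrapment proteins.
#'
#' @param is_entrapment Logical vector, descending-score order.
#' @return Numeric vector of running entrapment FDR values.
#' @export
entrapment_fdr <- function(is_entrapment) {
  if (!length(is_entrapment)) return(numeric(0))
  cumsum(is_entrapment) / seq_along(is_entrapment)
}

#' Decoy-FDR vs entrapment-FDR calibration curve
#'
#' Pairs the decoy-model q-values of a ranked target list with the observed
#' entrapment FDR at the same thresholds (one point per distinct q-value).
#' Also records the maximal multiplicative deviation from the identity line
#' over a stated decoy-FDR interval.
#'
#' @param q_values Decoy-model q-values of the accepted targets.
#' @param is_entrapment Logical entrapment annotation, parallel to
#'   `q_values`.
#' @param fdr_range Decoy-FDR interval over which the deviation statistic is
#'   evaluated (default `c(0.01, 0.1)`).
#' @return `data.frame` of class `calibration_curve` with columns
#'   `decoy_fdr`, `entrapment_fdr`, `n_sample`, `n_entrapment`; the maximal
#'   deviation is in `attr(, "max_deviation")`.
#' @export
calibration_curve <- function(q_values, is_entrapment,
                              fdr_range = c(0.01, 0.1)) {
  stopifnot(length(q_values) == length(is_entrapment))
  o <- order(q_values)
  q <- q_values[o]
  e <- is_entrapment[o]
  cum_e <- cumsum(e)
  n <- seq_along(q)
  last <- which(c(q[-1L] != q[-length(q)], TRUE))
  curve <- data.frame(decoy_fdr = q[last],
                      entrapment_fdr = cum_e[last] / n[last],
                      n_sample = n[last] - cum_e[last],
                      n_entrapment = cum_e[last])
  in_range <- curve$decoy_fdr >= fdr_range[1L] & curve$decoy_fdr <= fdr_range[2L]
  dev <- NA_real_
  if (any(in_range)) {
    r <- curve$entrapment_fdr[in_range] / curve$decoy_fdr[in_range]
    dev <- max(pmax(r, 1 / r))
  }
  attr(curve, "max_deviation") <- dev
  attr(curve, "fdr_range") <- fdr_range
  class(curve) <- c("calibration_curve", "data.frame")
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve: %d thresholds; max multiplicative deviation %.3g on decoy FDR in [%g, %g]\n",
              nrow(x), attr(x, "max_deviation"),
              attr(x, "fdr_range")[1L], attr(x, "fdr_range")[2L]))
  invisible(x)
}
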