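#' Target-decoy q-values
#'
#' For every score threshold t the false discovery rate is estimated as
#' `(1 + #decoys >= t) / #targets >= t` (the +1 pseudo-count is the standard
#' conservative target-decoy convention; no pi0 adjustment is applied). The
#' q-value of an entity is the minimum estimated FDR over all thresholds at
#' or below its score, capped at 1. Entities with tied scores are treated as
#' a single threshold and accepted or rejected together. Decoys are assigned
#' the q-value at their own score threshold (reporting only).
#'
#' @param score Numeric vector, higher is better; must be finite.
#' @param is_target Logical vector parallel to `score`.
#' @return Numeric vector of q-values in `[0, 1]`, in input order.
#' @export
#' @examples
#' td_qvalues(c(10, 9, 8, 7, 8.5, 6),
#'            c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
td_qvalues <- function(score, is_target) {
  stopifnot(length(score) == length(is_target), all(is.finite(score)),
            is.logical(is_target))
  if (!any(is_target)) stop("q-value estimation requires at least one target")
  n <- length(score)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  t <- is_target[o]
  cum_t <- cumsum(t)
  cum_d <- cumsum(!t)
  last <- which(c(s[-1L] != s[-n], TRUE))     # end of each tie block
  fdr <- (1 + cum_d[last]) / cum_t[last]
  fdr[cum_t[last] == 0L] <- Inf               # no target at/above threshold
  q_block <- pmin(rev(cummin(rev(fdr))), 1)
  block <- rep(seq_along(last), diff(c(0L, last)))
  q <- numeric(n)
  q[o] <- q_block[block]
  q
}

#' Posterior error probabilities from binned decoy/target ratios
#'
#' Entities are sorted by score into equal-count bins; the raw PEP of a bin
#' is `min(1, #decoys / #targets)` within it (using decoys as a model of the
#' incorrect-target score distribution, with pi0 = 1). Monotone
#' non-increase in score is then enforced by pool-adjacent-violators
#' (isotonic) regression and each entity receives its bin's monotonized
#' value. With fewer than 20 targets or 20 decoys a single global bin is
#' used.
#'
#' @param score Numeric vector, higher is better.
#' @param is_target Logical vector parallel to `score`.
#' @param n_bins Number of bins; default `max(20, floor(n / 500))`.
#' @return Numeric vector of PEPs in `[0, 1]`, in input order.
#' @export
estimate_peps <- function(score, is_target, n_bins = NULL) {
  stopifnot(length(score) == length(is_target), all(is.finite(score)))
  n <- length(score)
  if (is.null(n_bins)) n_bins <- max(20L, floor(n / 500))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  nt <- sum(is_target)
  nd <- n - nt
  if (nt < 20L || nd < 20L) {
    return(rep(min(1, nd / max(nt, 1L)), n))
  }
  o <- order(score)                            # ascending
  bin <- ceiling(seq_len(n) * n_bins / n)      # equal-count bins
  raw <- vapply(split(is_target[o], bin), function(tt) {
    min(1, sum(!tt) / max(sum(tt), 1L))
  }, numeric(1L))
  raw[vapply(split(is_target[o], bin), function(tt) !any(tt), logical(1L))] <- 1
  # PEP must be non-increasing in score: fit non-decreasing on reversed order
  iso <- rev(stats::isoreg(rev(raw))$yf)
  iso <- pmin(pmax(iso, 0), 1)
  pep <- numeric(n)
  pep[o] <- iso[bin]
  pep
}

#' Empirical p-values against a decoy score distribution
#'
#' `p = (1 + #(decoys >= score)) / (1 + #decoys)`; the +1 smoothing keeps
#' p strictly positive so the values are usable in Fisher's method.
#'
#' @param score Numeric vector of scores to evaluate.
#' @param decoy_scores Non-empty numeric vector of decoy (null) scores.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalues <- function(score, decoy_scores) {
  if (!length(decoy_scores)) stop("decoy score list must be non-empty")
  stopifnot(all(is.finite(score)), all(is.finite(decoy_scores)))
  sd_sorted <- sort(decoy_scores)
  nd <- length(sd_sorted)
  n_below <- findInterval(score, sd_sorted, left.open = TRUE)  # decoys < s
  (1 + (nd - n_below)) / (1 + nd)
}

#' Fisher's method for combining independent p-values
#'
#' `X = -2 * sum(log(p))` is referred to a chi-square distribution with
#' `2k` degrees of freedom (`k` p-values); the survival probability is
#' returned.
#'
#' @param p Non-empty numeric vector of p-values in `(0, 1]`.
#' @return A single combined p-value.
#' @export
#' @examples
#' fisher_combine(c(0.5, 0.5))  # 0.5966
fisher_combine <- function(p) {
  if (!length(p)) stop("p-value list must be non-empty")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("all p-values must lie in (0, 1]")
  }
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Full confidence table for a set of scored entities
#'
#' Convenience wrapper computing q-values, PEPs and (optionally) empirical
#' decoy p-values for a table of scored target/decoy entities.
#'
#' @param entities `data.frame` with columns `id`, `score` and logical
#'   `is_target`.
#' @param p_values Logical; also compute empirical p-values against the
#'   decoy scores (skipped when there are no decoys).
#' @param n_bins Passed to [estimate_peps()].
#' @return The input with `q_value`, `pep` and optionally `p_value` columns
#'   added, sorted by descending score.
#' @export
confidence_table <- function(entities, p_values = TRUE, n_bins = NULL) {
  stopifnot(all(c("id", "score", "is_target") %in% names(entities)))
  entities$q_value <- td_qvalues(entities$score, entities$is_target)
  entities$pep <- estimate_peps(entities$score, entities$is_target,
                                n_bins = n_bins)
  if (p_values && any(!entities$is_target)) {
    entities$p_value <- empirical_pvalues(
      entities$score, entities$score[!entities$is_target])
  }
  entities <- entities[order(-entities$score), , drop = FALSE]
  rownames(entities) <- NULL
  entities
}

#' Write a confidence table to TSV
#'
#' One row per entity, sorted by descending score, columns `id`, `label`,
#' `score`, `q_value`, `pep` (and `p_value` when present).
#'
#' @param tab Output of [confidence_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confidence_tsv <- function(tab, path) {
  out <- data.frame(id = tab$id,
                    label = ifelse(tab$is_target, "target", "decoy"),
                    score = tab$score, q_value = tab$q_value, pep = tab$pep,
                    stringsAsFactors = FALSE)
  if (!is.null(tab$p_value)) out$p_value <- tab$p_value
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
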