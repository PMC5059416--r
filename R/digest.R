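#' Proteolytic digestion parameters
#'
#' Bundles the cleavage rule used throughout the package. The default is
#' trypsin: cleavage after K or R, suppressed when the following residue is
#' proline, no missed cleavages, and peptide lengths of 7--50 residues (the
#' settings used for full-digestion benchmark searches).
#'
#' @param missed_cleavages Non-negative integer; maximum number of internal
#'   cleavage sites a reported peptide may span.
#' @param min_length,max_length Inclusive peptide length bounds in residues.
#' @param cleave_after Character vector of residues after which the enzyme
#'   cuts (default `c("K", "R")`).
#' @param suppress_proline Logical; if `TRUE`, a site is not cleaved when the
#'   next residue is `P`.
#' @return An object of class `digest_params`.
#' @export
#' @examples
#' digest("MKARPLTKSE", digest_params(min_length = 1))
digest_params <- function(missed_cleavages = 0L, min_length = 7L,
                          max_length = 50L, cleave_after = c("K", "R"),
                          suppress_proline = TRUE) {
  missed_cleavages <- as.integer(missed_cleavages)
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  if (missed_cleavages < 0L) stop("missed_cleavages must be >= 0")
  if (min_length < 1L) stop("min_length must be >= 1")
  if (max_length < min_length) stop("max_length must be >= min_length")
  structure(list(missed_cleavages = missed_cleavages,
                 min_length = min_length, max_length = max_length,
                 cleave_after = toupper(cleave_after),
                 suppress_proline = isTRUE(suppress_proline)),
            class = "digest_params")
}

#' @export
print.digest_params <- function(x, ...) {
  cat(sprintf("digestion: cleave after [%s]%s, <=%d missed cleavages, length %d-%d\n",
              paste(x$cleave_after, collapse = ""),
              if (x$suppress_proline) " (suppressed before P)" else "",
              x$missed_cleavages, x$min_length, x$max_length))
  invisible(x)
}

# 0-based cut positions (cut after residue i); sequence given as a char vector
cut_sites <- function(chars, params) {
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% params$cleave_after)
  if (params$suppress_proline && length(idx)) {
    idx <- idx[chars[idx + 1L] != "P"]
  }
  idx
}

# ordered base fragments (between consecutive cut sites), no length filter
base_fragments <- function(sequence, params) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  b <- c(0L, cut_sites(chars, params), length(chars))
  substring(sequence, b[-length(b)] + 1L, b[-1L])
}

#' In-silico digestion of a protein sequence
#'
#' Cleaves a sequence at every enzymatic site (after K/R for trypsin, with
#' optional proline suppression), concatenates up to
#' `missed_cleavages + 1` adjacent fragments, applies the length filter and
#' returns the distinct peptides. Non-standard residues (B, Z, U, X, ...) are
#' digested literally: they are ordinary non-cleaving characters.
#'
#' @param sequence Non-empty amino-acid string.
#' @param params A [digest_params()] object.
#' @return Character vector of distinct peptides (possibly empty), sorted.
#' @export
digest <- function(sequence, params = digest_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  frags <- base_fragments(sequence, params)
  nf <- length(frags)
  lens <- nchar(frags)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  peps <- character(0)
  for (span in seq_len(min(params$missed_cleavages, nf - 1L) + 1L)) {
    i <- seq_len(nf - span + 1L)
    len <- ends[i + span - 1L] - starts[i] + 1L
    keep <- len >= params$min_length & len <= params$max_length
    if (any(keep)) {
      peps <- c(peps, substring(sequence, starts[i][keep],
                                ends[i + span - 1L][keep]))
    }
  }
  sort(unique(peps))
}

# digest many proteins at once -> named list of peptide vectors
digest_proteins <- function(proteins, params = digest_params()) {
  sets <- lapply(proteins$sequence, digest, params = params)
  names(sets) <- proteins$id
  sets
}

# inverted index: peptide -> character vector of protein/group ids
peptide_index <- function(sets) {
  if (!length(sets)) return(list(peptide = character(0), ids = list()))
  pep <- unlist(sets, use.names = FALSE)
  owner <- rep(names(sets), lengths(sets))
  split(owner, pep)
}
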