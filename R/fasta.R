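#' Read a protein FASTA database
#'
#' Parses a FASTA file into a protein table. The accession is the header
#' token before the first whitespace; sequences are uppercased with line
#' breaks removed. Records whose accession starts with `decoy_prefix` are
#' flagged as decoys.
#'
#' @param path Path to a FASTA file.
#' @param decoy_prefix Accession prefix marking decoy entries
#'   (default `"rev_"`).
#' @return A `data.frame` with columns `id`, `sequence`, `is_decoy`.
#' @export
read_fasta <- function(path, decoy_prefix = "rev_") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) &&
      !startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA: sequence before header at line ", nonblank[1L])
  }
  if (!length(nonblank)) {
    return(data.frame(id = character(0), sequence = character(0),
                      is_decoy = logical(0), stringsAsFactors = FALSE))
  }
  aa <- Biostrings::readAAStringSet(path)
  id <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(id)) {
    stop("duplicate protein ids in FASTA: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ", paste(id[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(id = id, sequence = unname(seqs),
             is_decoy = startsWith(id, decoy_prefix),
             stringsAsFactors = FALSE)
}

#' Write a protein table to FASTA
#'
#' @param proteins `data.frame` with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Reverse protein sequences to build a decoy database
#'
#' Each target sequence is reversed in full and its accession is prefixed,
#' the conventional construction of a reversed decoy database.
#'
#' @param proteins Protein `data.frame` (see [read_fasta()]).
#' @param prefix Decoy accession prefix (default `"rev_"`).
#' @return Protein `data.frame` of decoys with `is_decoy = TRUE`.
#' @export
reverse_proteins <- function(proteins, prefix = "rev_") {
  rev_seq <- vapply(strsplit(proteins$sequence, "", fixed = TRUE),
                    function(ch) paste(rev(ch), collapse = ""), character(1L))
  data.frame(id = paste0(prefix, proteins$id), sequence = rev_seq,
             is_decoy = TRUE, stringsAsFactors = FALSE)
}
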