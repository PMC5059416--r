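#' Read a PIN (Percolator input) tab-delimited PSM table
#'
#' Expected header: `SpecId  Label  ScanNr  <feature columns...>  Peptide
#' Proteins`, with `Label` in `{1, -1}` and any protein accessions beyond
#' the `Proteins` column position collected into a list. An optional second
#' line starting with `DefaultDirection` is parsed and ignored.
#'
#' @param path Path to a PIN file.
#' @return A `data.frame` of class `psm_set` with columns `spec_id`,
#'   `is_target`, `scan`, one numeric column per feature, `peptide`
#'   (flanks retained verbatim) and list column `proteins`. The feature
#'   column names are stored in `attr(, "feature_names")`.
#' @export
read_pin <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PIN file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("SpecId", "Label", "ScanNr", "Peptide", "Proteins")
  if (!all(need %in% header)) {
    stop("PIN header must contain: ", paste(need, collapse = ", "))
  }
  pep_col <- match("Peptide", header)
  feat_cols <- seq(match("ScanNr", header) + 1L, pep_col - 1L)
  body <- lines[-1L]
  if (length(body) && startsWith(body[[1L]], "DefaultDirection")) {
    body <- body[-1L]
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  if (length(cells) && any(lengths(cells) < pep_col + 1L)) {
    stop("PIN row with too few columns at data line ",
         which(lengths(cells) < pep_col + 1L)[1L])
  }
  get <- function(i) vapply(cells, `[[`, character(1L), i)
  feats <- lapply(feat_cols, function(i) as.numeric(get(i)))
  names(feats) <- header[feat_cols]
  psms <- data.frame(spec_id = if (length(cells)) get(match("SpecId", header)) else character(0),
                     is_target = if (length(cells)) get(match("Label", header)) == "1" else logical(0),
                     scan = if (length(cells)) as.integer(get(match("ScanNr", header))) else integer(0),
                     stringsAsFactors = FALSE)
  for (nm in names(feats)) psms[[nm]] <- feats[[nm]]
  psms$peptide <- if (length(cells)) get(pep_col) else character(0)
  psms$proteins <- lapply(cells, function(x) x[seq(pep_col + 1L, length(x))])
  attr(psms, "feature_names") <- header[feat_cols]
  class(psms) <- c("psm_set", "data.frame")
  psms
}

#' Write a PSM table in PIN format
#'
#' @param psms A `psm_set` table (see [read_pin()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pin <- function(psms, path) {
  feat <- attr(psms, "feature_names")
  header <- c("SpecId", "Label", "ScanNr", feat, "Peptide", "Proteins")
  prot <- vapply(psms$proteins, paste, character(1L), collapse = "\t")
  rows <- cbind(psms$spec_id, ifelse(psms$is_target, "1", "-1"),
                as.character(psms$scan),
                vapply(feat, function(f) format(psms[[f]], digits = 17,
                                                trim = TRUE, scientific = FALSE),
                       character(nrow(psms))),
                psms$peptide, prot)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(psms)) writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Strip flanking residues and modification annotations from a peptide
#'
#' PIN peptides carry flanking residues (`K.PEPTIDE.R`) and may carry
#' modification annotations in square brackets (`PEPT[15.99]IDE`). Matching
#' against theoretical (unmodified) digests uses the bare uppercase
#' sequence.
#'
#' @param peptide Character vector of PIN peptide strings.
#' @return Character vector of bare peptide sequences.
#' @export
strip_peptide <- function(peptide) {
  x <- sub("^.\\.", "", peptide)
  x <- sub("\\..$", "", x)
  toupper(gsub("\\[[^]]*\\]", "", x))
}
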