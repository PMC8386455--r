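#' Protein record
#'
#' A single amino-acid sequence with an identifier and optional taxon and
#' sample labels. Sequences are uppercased on ingest; \code{*} stop characters
#' are stripped with a warning; characters outside the 20 standard residues
#' plus \code{X} are rejected.
#'
#' @param id identifier (first whitespace-separated token is used).
#' @param sequence amino-acid string.
#' @param taxon,source_sample optional labels.
#' @export
protein_record <- function(id, sequence, taxon = NA_character_,
                           source_sample = NA_character_) {
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  structure(list(id = as.character(id), sequence = clean_sequence(sequence),
                 taxon = taxon, source_sample = source_sample),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (!is.na(x$taxon)) paste0(" taxon=", x$taxon) else ""))
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet}; the first token of
#' each header is taken as the record id.
#'
#' @param path FASTA file (wrapped or single-line).
#' @return a named list of \code{\link{protein_record}} objects.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  recs <- lapply(seq_along(ss), function(i)
    protein_record(ids[i], as.character(ss[[i]])))
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA
#'
#' @param records list of \code{protein_record}.
#' @param path output path.
#' @export
write_proteins <- function(records, path) {
  seqs <- vapply(records, function(r) r$sequence, "")
  names(seqs) <- vapply(records, function(r) r$id, "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 70L)
  invisible(path)
}
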