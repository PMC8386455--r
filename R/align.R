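#' Pairwise protein alignment with affine gap penalties
#'
#' \code{global_align()} computes an optimal Needleman-Wunsch global alignment;
#' \code{local_align()} an optimal Smith-Waterman local alignment. Gaps are
#' affine: a run of L gap columns costs \code{gap_open + (L - 1) * gap_extend},
#' i.e. the first column of a gap pays the full opening penalty (BLASTP's
#' convention, so the defaults open = 11 / extend = 1 match BLASTP defaults).
#' Traceback ties are broken deterministically: diagonal first, then a gap in
#' the target, then a gap in the query.
#'
#' Input is case-insensitive; sequences are uppercased and any \code{*} stop
#' characters are stripped with a warning.
#'
#' @param a,b protein sequences (single strings over the 20 standard residues
#'   plus \code{X}), or \code{protein_record} objects.
#' @param matrix a \code{\link{substitution_matrix}}.
#' @param gap_open,gap_extend nonnegative penalties, \code{gap_open >= gap_extend}.
#' @return an object of class \code{"pairwise_alignment"}: a list with
#'   \code{query_id}, \code{target_id}, \code{aligned_query},
#'   \code{aligned_target}, \code{score}, \code{mode}, \code{query_span},
#'   \code{target_span}, \code{query_length}, \code{target_length}.
#'   A local alignment with no positive-scoring residue pair has score 0,
#'   empty aligned strings and \code{NA} spans.
#' @examples
#' aln <- global_align("MKT", "MRT")
#' aln$score  # 12 under BLOSUM62: M:M 5, K:R 2, T:T 5
#' @export
global_align <- function(a, b, matrix = substitution_matrix(),
                         gap_open = 11, gap_extend = 1) {
  .align(a, b, matrix, gap_open, gap_extend, local = FALSE)
}

#' @rdname global_align
#' @export
local_align <- function(a, b, matrix = substitution_matrix(),
                        gap_open = 11, gap_extend = 1) {
  .align(a, b, matrix, gap_open, gap_extend, local = TRUE)
}

.seq_of <- function(x, what) {
  if (inherits(x, "protein_record")) return(list(id = x$id, seq = x$sequence))
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("'", what, "' must be a single protein sequence string")
  list(id = what, seq = clean_sequence(x))
}

# uppercase, strip '*' with a warning, validate alphabet
clean_sequence <- function(s) {
  s <- toupper(s)
  if (grepl("*", s, fixed = TRUE)) {
    warning("stripping '*' stop character(s) from sequence")
    s <- gsub("*", "", s, fixed = TRUE)
  }
  bad <- setdiff(unique(strsplit(s, "")[[1]]), strsplit(aa_alphabet(), "")[[1]])
  if (length(bad))
    stop("invalid character '", bad[1L], "' in sequence")
  s
}

.align <- function(a, b, matrix, gap_open, gap_extend, local) {
  qa <- .seq_of(a, "query"); qb <- .seq_of(b, "target")
  if (!nzchar(qa$seq) || !nzchar(qb$seq)) stop("empty sequence: alignment requires nonempty input")
  if (gap_extend < 0 || gap_open < gap_extend)
    stop("require gap_open >= gap_extend >= 0")
  if (!inherits(matrix, "substitution_matrix")) matrix <- substitution_matrix("custom", matrix)
  res <- .align_pair_cpp(qa$seq, qb$seq, unclass(matrix), aa_alphabet(),
                         gap_open, gap_extend, local)
  structure(list(
    query_id = qa$id, target_id = qb$id,
    aligned_query = res$aligned_a, aligned_target = res$aligned_b,
    score = res$score, mode = if (local) "local" else "global",
    query_span = res$a_span, target_span = res$b_span,
    query_length = nchar(qa$seq), target_length = nchar(qb$seq),
    gap_open = gap_open, gap_extend = gap_extend
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: %s vs %s\n", x$mode, x$query_id, x$target_id))
  cat(sprintf("score: %g  spans: query %s-%s, target %s-%s\n", x$score,
              x$query_span[1], x$query_span[2], x$target_span[1], x$target_span[2]))
  if (nzchar(x$aligned_query)) {
    cat(x$aligned_query, "\n")
    cat(x$aligned_target, "\n")
  } else cat("(empty alignment)\n")
  invisible(x)
}

#' Rescore an emitted alignment
#'
#' Recomputes the score of a gapped alignment from its two gapped strings under
#' the same matrix and penalties; used to check that the DP's reported score is
#' consistent with the alignment it emits.
#'
#' @param aln a \code{pairwise_alignment}.
#' @param matrix substitution matrix (default BLOSUM62).
#' @return numeric score.
#' @export
alignment_score <- function(aln, matrix = substitution_matrix()) {
  qa <- strsplit(aln$aligned_query, "")[[1]]
  qb <- strsplit(aln$aligned_target, "")[[1]]
  if (length(qa) != length(qb)) stop("gapped strings differ in length")
  if (length(qa) == 0L) return(0)
  sc <- 0; in_gap <- ""
  for (k in seq_along(qa)) {
    ca <- qa[k]; cb <- qb[k]
    if (ca == "-" && cb == "-") stop("gap-gap column")
    if (ca == "-" || cb == "-") {
      side <- if (ca == "-") "q" else "t"
      sc <- sc - if (identical(in_gap, side)) aln$gap_extend else aln$gap_open
      in_gap <- side
    } else {
      sc <- sc + matrix[ca, cb]
      in_gap <- ""
    }
  }
  sc
}

#' Percent identity of a pairwise alignment
#'
#' Counts columns with identical residues (gap columns never match) and divides
#' by the chosen denominator. The default, the length of the shorter sequence,
#' is the convention cd-hit clusters with, and the one the package's 82\%
#' OTU threshold is applied under.
#'
#' @param aln a \code{pairwise_alignment}.
#' @param denominator \code{"shorter_seq"} (full length of the shorter input
#'   sequence) or \code{"alignment_columns"}.
#' @return a fraction in [0, 1].
#' @export
percent_identity <- function(aln, denominator = c("shorter_seq", "alignment_columns")) {
  denominator <- match.arg(denominator)
  qa <- strsplit(aln$aligned_query, "")[[1]]
  qb <- strsplit(aln$aligned_target, "")[[1]]
  matches <- sum(qa == qb & qa != "-")
  den <- switch(denominator,
                shorter_seq = min(aln$query_length, aln$target_length),
                alignment_columns = length(qa))
  if (den == 0L) stop("undefined identity: zero-length denominator")
  matches / den
}

#' Write alignments as a tab-separated table
#'
#' @param alignments a list of \code{pairwise_alignment} objects.
#' @param path output TSV path.
#' @export
write_alignment_table <- function(alignments, path) {
  df <- do.call(rbind, lapply(alignments, function(a) {
    data.frame(query_id = a$query_id, target_id = a$target_id, mode = a$mode,
               score = a$score, identity = percent_identity(a),
               query_start = a$query_span[1], query_end = a$query_span[2],
               target_start = a$target_span[1], target_end = a$target_span[2],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
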