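#' Screening configuration
#'
#' Parameters of the proteorhodopsin candidate screen. \code{min_length_aa}
#' defaults to 100 and is applied strictly ("larger than 100 amino acids":
#' a 100-aa protein fails). \code{evalue_max_import} (default 1e-7) filters
#' imported external similarity-search hits.
#'
#' @param min_length_aa minimum protein length, exclusive.
#' @param min_bitlike_score score threshold for the internal local-alignment
#'   search.
#' @param evalue_max_import maximum E value kept when importing external hits.
#' @export
screen_config <- function(min_length_aa = 100L, min_bitlike_score = 50,
                          evalue_max_import = 1e-7) {
  if (min_length_aa <= 0) stop("min_length_aa must be positive")
  if (evalue_max_import <= 0) stop("evalue_max_import must be positive")
  structure(list(min_length_aa = as.integer(min_length_aa),
                 min_bitlike_score = min_bitlike_score,
                 evalue_max_import = evalue_max_import),
            class = "screen_config")
}

#' Search queries against a reference panel by local alignment
#'
#' An internal convenience stand-in for an external similarity search: every
#' query is locally aligned against every panel member and the best hit is
#' reported. Queries whose best score falls below \code{min_bitlike_score}
#' are dropped. Ties are broken by the lexicographically smaller hit id.
#'
#' @param queries list of \code{protein_record}.
#' @param panel nonempty list of \code{protein_record} (the reference panel).
#' @param cfg a \code{\link{screen_config}}.
#' @param ... passed to \code{\link{local_align}}.
#' @return data.frame(query_id, best_hit_id, score), one row per retained
#'   query, in input order.
#' @export
search_candidates <- function(queries, panel, cfg = screen_config(), ...) {
  if (length(panel) == 0L) stop("configuration error: empty reference panel")
  if (inherits(queries, "protein_record")) queries <- list(queries)
  panel_ids <- vapply(panel, function(p) p$id, "")
  ord <- order(panel_ids)          # lexicographic tie-break
  panel <- panel[ord]; panel_ids <- panel_ids[ord]
  rows <- lapply(queries, function(q) {
    scores <- vapply(panel, function(p) local_align(q, p, ...)$score, 0)
    best <- which.max(scores)      # first max = lexicographically smallest id
    data.frame(query_id = q$id, best_hit_id = panel_ids[best],
               score = scores[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$score >= cfg$min_bitlike_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import an external similarity-search hit table
#'
#' Reads a BLAST/DIAMOND outfmt-6-style tab-separated table, keeps rows with
#' E value at or below \code{evalue_max_import} (default 1e-7) and reports the
#' best hit per query (lowest E value, ties broken by highest bitscore).
#' Column names \code{query_id}/\code{subject_id} or \code{qseqid}/\code{sseqid}
#' are accepted.
#'
#' @param hit_table path to a TSV with a header, or a data.frame.
#' @param cfg a \code{\link{screen_config}}.
#' @return data.frame(query_id, best_hit_id, evalue, bitscore).
#' @export
import_external_hits <- function(hit_table, cfg = screen_config()) {
  df <- if (is.data.frame(hit_table)) hit_table else
    utils::read.delim(hit_table, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  if ("qseqid" %in% nm) names(df)[nm == "qseqid"] <- "query_id"
  if ("sseqid" %in% names(df)) names(df)[names(df) == "sseqid"] <- "subject_id"
  for (col in c("query_id", "subject_id", "evalue", "bitscore"))
    if (!col %in% names(df))
      stop("format error: hit table is missing column '", col, "'")
  ev <- suppressWarnings(as.numeric(df$evalue))
  if (anyNA(ev)) {
    bad <- which(is.na(ev))[1L]
    stop("unparseable evalue at line ", bad + 1L, ": '", df$evalue[bad], "'")
  }
  df$evalue <- ev
  df <- df[df$evalue <= cfg$evalue_max_import, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(query_id = character(), best_hit_id = character(),
                      evalue = numeric(), bitscore = numeric()))
  df <- df[order(df$query_id, df$evalue, -df$bitscore), ]
  best <- df[!duplicated(df$query_id), ]
  data.frame(query_id = best$query_id, best_hit_id = best$subject_id,
             evalue = best$evalue, bitscore = best$bitscore,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Curate proteorhodopsin candidates
#'
#' Applies the two curation rules to each candidate: the protein must be
#' larger than \code{min_length_aa} amino acids, and its global alignment to
#' the annotated reference must cover the proton-pumping C-helix region —
#' operationally, at least 3 of the 4 key positions (97, 101, 105, 108) align
#' to non-gap query residues. Residue identity at the triad is deliberately
#' NOT a curation criterion (a pump-triad variant such as K108 is retained and
#' reported downstream as non-canonical).
#'
#' @param candidates list of \code{protein_record}.
#' @param reference an \code{\link{annotated_reference}} (default: bundled).
#' @param cfg a \code{\link{screen_config}}.
#' @param ... passed to the aligner.
#' @return data.frame(query_id, length_aa, passed_length,
#'   domain_region_covered, retained, reason); \code{reason} names the failing
#'   rule(s), empty when retained.
#' @export
curate_candidates <- function(candidates, reference = pr_reference(),
                              cfg = screen_config(), ...) {
  if (inherits(candidates, "protein_record")) candidates <- list(candidates)
  rows <- lapply(candidates, function(rec) {
    len <- nchar(rec$sequence)
    passed_length <- len > cfg$min_length_aa
    mapped <- tryCatch(map_reference_positions(rec, reference, ...),
                       error = function(e) stats::setNames(
                         rep(NA_integer_, 4L), names(reference$key_positions)))
    covered <- sum(!is.na(mapped)) >= 3L
    reason <- c(if (!passed_length) sprintf("length %d <= %d aa", len, cfg$min_length_aa),
                if (!covered) "C-helix region not covered")
    data.frame(query_id = rec$id, length_aa = len,
               passed_length = passed_length, domain_region_covered = covered,
               retained = passed_length && covered,
               reason = paste(reason, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
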