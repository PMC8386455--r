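#' Annotated proteorhodopsin reference
#'
#' A reference protein carrying the proton-pumping triad positions (97, 101,
#' 108) and the spectral-tuning position (105) in proteorhodopsin numbering.
#' The reference anchors the coordinate system: "position 97" always means the
#' 97th annotated index of this record, and query residues are reported after
#' mapping onto it by global alignment.
#'
#' The canonical triad is aspartate-97 (proton acceptor), threonine-101 and
#' glutamate-108 (proton donor); the residue at 105 tunes the absorption
#' spectrum (leucine/methionine: green; glutamine: blue).
#'
#' @param record a \code{\link{protein_record}}.
#' @param key_positions named integer vector mapping \code{"97"},
#'   \code{"101"}, \code{"105"}, \code{"108"} to 1-based indices in the
#'   reference sequence.
#' @return an object of class \code{"annotated_reference"}.
#' @export
annotated_reference <- function(record,
                                key_positions = c("97" = 97L, "101" = 101L,
                                                  "105" = 105L, "108" = 108L)) {
  stopifnot(inherits(record, "protein_record"))
  pos <- c("97", "101", "105", "108")
  if (!all(pos %in% names(key_positions)))
    stop("key_positions must name 97, 101, 105 and 108")
  idx <- as.integer(key_positions[pos])
  if (any(diff(idx) <= 0)) stop("key position indices must be strictly increasing")
  if (any(idx < 1L) || any(idx > nchar(record$sequence)))
    stop("key position index outside the reference sequence")
  res <- substring(record$sequence, idx, idx)
  expected <- c("97" = "D", "101" = "T", "108" = "E")
  for (p in names(expected))
    if (res[match(p, pos)] != expected[p])
      stop("reference residue at position ", p, " is ", res[match(p, pos)],
           ", expected ", expected[p])
  structure(list(record = record, key_positions = stats::setNames(idx, pos)),
            class = "annotated_reference")
}

#' The bundled synthetic reference
#'
#' Loads the package's synthetic canonical-like proteorhodopsin reference
#' (249 aa, D97/T101/L105/E108). It is a constructed stand-in, not a natural
#' sequence: its residue indices define the package's reference numbering.
#'
#' @return an \code{\link{annotated_reference}}.
#' @export
pr_reference <- function() {
  path <- system.file("extdata", "pr_reference_synthetic.fasta",
                      package = "rhodoquant", mustWork = TRUE)
  annotated_reference(read_proteins(path)[[1L]])
}

#' Map reference key positions onto a query protein
#'
#' Globally aligns the query to the reference and reports, for each key
#' position, the 1-based query index aligned to it, or \code{NA} when the
#' reference position sits opposite a gap.
#'
#' @param query a \code{protein_record} (or sequence string).
#' @param ref an \code{\link{annotated_reference}}.
#' @param positions which reference positions to map (default the four key ones).
#' @param ... passed to \code{\link{global_align}}.
#' @return named integer vector (names = positions; \code{NA} = gap).
#' @export
map_reference_positions <- function(query, ref, positions = names(ref$key_positions), ...) {
  aln <- global_align(query, ref$record, ...)
  qa <- strsplit(aln$aligned_query, "")[[1]]
  qt <- strsplit(aln$aligned_target, "")[[1]]
  ref_idx <- cumsum(qt != "-")
  qry_idx <- cumsum(qa != "-")
  out <- stats::setNames(rep(NA_integer_, length(positions)), positions)
  for (p in positions) {
    tgt <- ref$key_positions[[p]]
    col <- which(ref_idx == tgt & qt != "-")[1L]
    if (!is.na(col) && qa[col] != "-") out[p] <- qry_idx[col]
  }
  out
}

#' Proton-pump functionality call from triad residues
#'
#' \code{"functional"} iff the residues at 97/101/108 are exactly D, T, E
#' (the canonical proton-pumping triad); \code{"non_canonical"} when all three
#' are mapped but any differs (e.g. a lysine in place of glutamate-108);
#' \code{"undetermined"} when any position maps to a gap.
#'
#' @param res97,res101,res108 single residues or \code{NA} for gap.
#' @return character call.
#' @export
classify_pump <- function(res97, res101, res108) {
  r <- c(res97, res101, res108)
  if (anyNA(r)) return("undetermined")
  if (identical(unname(r), c("D", "T", "E"))) "functional" else "non_canonical"
}

#' Spectral-tuning call from the residue at position 105
#'
#' Leucine or methionine: \code{"green"}; glutamine: \code{"blue"}; a gap:
#' \code{"undetermined"}; any other residue: \code{"unknown"} (never coerced
#' to a color).
#'
#' @param res105 single residue or \code{NA} for gap.
#' @return character call.
#' @export
classify_color <- function(res105) {
  if (is.na(res105)) return("undetermined")
  if (res105 %in% c("L", "M")) "green" else if (res105 == "Q") "blue" else "unknown"
}

#' Annotate proteins at the proteorhodopsin key positions
#'
#' Maps every record onto the reference numbering and reports the residues at
#' 97/101/105/108 together with the pump and color calls.
#'
#' @param records list of \code{protein_record} (or a single one).
#' @param ref an \code{\link{annotated_reference}} (default: bundled).
#' @param ... passed to the aligner.
#' @return a data.frame with columns \code{query_id}, \code{res97},
#'   \code{res101}, \code{res105}, \code{res108}, \code{pump_call},
#'   \code{color_call}. Gap residues are \code{NA}.
#' @export
annotate_proteins <- function(records, ref = pr_reference(), ...) {
  if (inherits(records, "protein_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    m <- map_reference_positions(rec, ref, ...)
    res <- vapply(names(m), function(p) {
      if (is.na(m[[p]])) NA_character_ else substring(rec$sequence, m[[p]], m[[p]])
    }, "")
    data.frame(query_id = rec$id,
               res97 = res[["97"]], res101 = res[["101"]],
               res105 = res[["105"]], res108 = res[["108"]],
               pump_call = classify_pump(res[["97"]], res[["101"]], res[["108"]]),
               color_call = classify_color(res[["105"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-position residue frequency profile
#'
#' Residue counts and frequencies at one key position across a set of
#' annotations (the data behind a sequence-logo view of the proton-pumping
#' domain). Gaps are excluded from the frequencies and counted separately.
#'
#' @param annotations data.frame from \code{\link{annotate_proteins}}.
#' @param position one of 97, 101, 105, 108.
#' @return list with \code{position}, \code{counts}, \code{frequencies},
#'   \code{gap_count}.
#' @export
position_profile <- function(annotations, position) {
  position <- as.character(position)
  col <- paste0("res", position)
  if (!col %in% names(annotations)) stop("position must be one of 97, 101, 105, 108")
  if (nrow(annotations) == 0L) stop("empty annotation set: no profile to compute")
  res <- annotations[[col]]
  gap_count <- sum(is.na(res))
  res <- res[!is.na(res)]
  counts <- table(res)
  list(position = as.integer(position),
       counts = stats::setNames(as.integer(counts), names(counts)),
       frequencies = stats::setNames(as.numeric(counts) / sum(counts), names(counts)),
       gap_count = gap_count)
}

#' Write annotations to TSV
#' @param annotations data.frame from \code{\link{annotate_proteins}}.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "GAP")
  invisible(path)
}
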