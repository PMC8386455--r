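#' Housekeeping-normalised relative expression
#'
#' For one metatranscriptome sample, the length-normalised transcript coverage
#' of the target (a gene class such as \code{"PR"}, \code{"blh"},
#' \code{"crtB"}, \code{"crtY"}, or a single gene id) is divided by the mean
#' transcript coverage of the three housekeeping families rplB, rpoB and
#' EF-Tu. recA is rejected as an RNA normaliser. The statistic is invariant to
#' sequencing depth, and the three housekeeping families themselves average
#' to exactly 1 under it.
#'
#' @param table gene count table of transcript counts
#'   (see \code{\link{read_gene_counts}}).
#' @param sample_id sample to evaluate.
#' @param target gene class or gene id.
#' @param hk_families RNA housekeeping families (default rplB, rpoB, EF-Tu).
#' @return list with \code{sample_id}, \code{target},
#'   \code{relative_expression}.
#' @export
transcript_relative_abundance <- function(table, sample_id, target,
                                          hk_families = hk_families_rna()) {
  if ("recA" %in% hk_families)
    stop("configuration error: recA is not a valid RNA housekeeping normalizer")
  table <- read_gene_counts(table)
  rows <- .sample_rows(table, sample_id)
  hk_cov <- vapply(hk_families, function(h) .family_coverage(rows, h), 0)
  if (any(hk_cov <= 0))
    stop("degenerate normalizer: housekeeping family '",
         hk_families[which(hk_cov <= 0)[1L]], "' has zero transcript coverage")
  sel <- if (target %in% rows$gene_class) rows$gene_class == target
         else rows$gene_id == target
  if (!any(sel)) stop("target '", target, "' not found in sample '", sample_id, "'")
  tgt_cov <- sum(gene_coverage(rows$count[sel], rows$gene_length[sel]))
  list(sample_id = sample_id, target = target,
       relative_expression = tgt_cov / mean(hk_cov))
}

#' Blue/green partition of proteorhodopsin transcripts
#'
#' Splits the PR transcript coverage of one sample by spectral color:
#' \code{blue_fraction} is blue PR coverage over the colored (blue + green)
#' total, likewise \code{green_fraction}; PR coverage with unknown or missing
#' color is reported separately and excluded from the denominator.
#'
#' @param table transcript count table with a \code{color} column on PR rows.
#' @param sample_id sample to evaluate.
#' @return list with \code{sample_id}, \code{blue_fraction},
#'   \code{green_fraction}, \code{unknown_mass}.
#' @export
color_transcript_partition <- function(table, sample_id) {
  table <- read_gene_counts(table)
  rows <- .sample_rows(table, sample_id)
  pr <- rows[rows$gene_class == "PR", , drop = FALSE]
  cov <- gene_coverage(pr$count, pr$gene_length)
  blue <- sum(cov[!is.na(pr$color) & pr$color == "blue"])
  green <- sum(cov[!is.na(pr$color) & pr$color == "green"])
  unknown <- sum(cov) - blue - green
  if (blue + green <= 0)
    stop("degenerate partition: no colored PR transcript coverage in '",
         sample_id, "'")
  list(sample_id = sample_id,
       blue_fraction = blue / (blue + green),
       green_fraction = green / (blue + green),
       unknown_mass = unknown)
}

#' Fold ratio between two relative-expression results
#'
#' @param expr_a,expr_b results of \code{\link{transcript_relative_abundance}}
#'   from the same sample.
#' @return expr_a / expr_b (positive number).
#' @export
gene_fold_ratio <- function(expr_a, expr_b) {
  if (!identical(expr_a$sample_id, expr_b$sample_id))
    stop("mismatch: fold ratios compare expression within one sample")
  if (expr_b$relative_expression <= 0)
    stop("degenerate: zero denominator expression")
  expr_a$relative_expression / expr_b$relative_expression
}
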