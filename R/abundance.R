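#' Gene count table
#'
#' Reads and validates the per-sample, per-gene count table consumed by the
#' abundance and transcription estimators. Required columns: \code{sample_id},
#' \code{gene_id}, \code{gene_class} (PR, recA, rplB, rpoB, EF-Tu, blh, crtB,
#' crtY or other), \code{gene_length} (nt, > 0), \code{count} (>= 0).
#' Optional: \code{otu_id}, \code{color}. (sample_id, gene_id) must be unique.
#'
#' @param x TSV path or data.frame.
#' @return validated data.frame.
#' @export
read_gene_counts <- function(x) {
  df <- if (is.data.frame(x)) x else
    utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "gene_id", "gene_class", "gene_length", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("count table is missing column '", miss[1L], "'")
  if (any(df$gene_length <= 0)) stop("gene_length must be positive")
  if (any(df$count < 0)) stop("counts must be nonnegative")
  if (anyDuplicated(df[c("sample_id", "gene_id")]))
    stop("(sample_id, gene_id) pairs must be unique")
  if (!"otu_id" %in% names(df)) df$otu_id <- NA_character_
  if (!"color" %in% names(df)) df$color <- NA_character_
  df
}

#' Single-copy housekeeping gene sets
#'
#' The four single-copy markers used to normalise metagenomic abundance
#' (recA, rplB, rpoB, EF-Tu) and the three used for metatranscriptomes.
#' recA is excluded from the RNA set because it is not constitutively
#' expressed in these waters, so it normalises gene abundance only.
#'
#' @name housekeeping_sets
#' @export
hk_families_dna <- function() c("recA", "rplB", "rpoB", "EF-Tu")

#' @rdname housekeeping_sets
#' @export
hk_families_rna <- function() c("rplB", "rpoB", "EF-Tu")

#' Length-normalised coverage of a gene
#'
#' Reads recruited to a gene divided by the gene length; proportional to the
#' gene's per-cell copy number times the carrying cells' abundance.
#'
#' @param count nonnegative read count (vectorised).
#' @param gene_length positive length.
#' @return count / gene_length.
#' @examples gene_coverage(100, 1000)  # 0.1
#' @export
gene_coverage <- function(count, gene_length) {
  if (any(gene_length <= 0)) stop("invalid input: gene_length must be positive")
  if (any(count < 0)) stop("invalid input: count must be nonnegative")
  count / gene_length
}

# total coverage of one gene family in one sample's rows
.family_coverage <- function(rows, family) {
  sel <- rows$gene_class == family
  sum(gene_coverage(rows$count[sel], rows$gene_length[sel]))
}

.sample_rows <- function(table, sample_id) {
  rows <- table[table$sample_id == sample_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("sample not found: '", sample_id, "'")
  rows
}

#' Fraction of proteorhodopsin-bearing bacteria in a metagenome
#'
#' For one sample, total PR coverage is divided by the total coverage of each
#' single-copy housekeeping family, and the four ratios are averaged. Because
#' every genome carries one copy of each housekeeping gene and PR-bearing
#' genomes carry one PR copy, each ratio estimates the fraction of cells
#' carrying PR, and the mean is the reported estimate. Estimates above 1 are
#' flagged, never clamped.
#'
#' @param table a gene count table (see \code{\link{read_gene_counts}}).
#' @param sample_id sample to evaluate.
#' @param hk_families housekeeping families used as denominators (default the
#'   DNA set recA, rplB, rpoB, EF-Tu).
#' @return list with \code{sample_id}, \code{per_housekeeping_ratio} (named),
#'   \code{pr_fraction}, \code{flag_gt1}.
#' @export
pr_bearing_fraction <- function(table, sample_id, hk_families = hk_families_dna()) {
  table <- read_gene_counts(table)
  rows <- .sample_rows(table, sample_id)
  c_pr <- .family_coverage(rows, "PR")
  ratios <- stats::setNames(numeric(length(hk_families)), hk_families)
  for (h in hk_families) {
    c_h <- .family_coverage(rows, h)
    if (c_h <= 0)
      stop("degenerate normalizer: housekeeping family '", h,
           "' has zero coverage in sample '", sample_id, "'")
    ratios[h] <- c_pr / c_h
  }
  frac <- mean(ratios)
  list(sample_id = sample_id, per_housekeeping_ratio = ratios,
       pr_fraction = frac, flag_gt1 = frac > 1)
}

#' Relative abundance of proteorhodopsin OTUs in one sample
#'
#' Per-OTU coverage (sum of member PR gene coverages, i.e. corrected for gene
#' size) divided by total PR coverage. Fractions sum to 1. PR genes without an
#' OTU assignment are dropped with a warning.
#'
#' @param table gene count table.
#' @param sample_id sample to evaluate.
#' @return named numeric vector of OTU shares.
#' @export
otu_relative_abundance <- function(table, sample_id) {
  table <- read_gene_counts(table)
  rows <- .sample_rows(table, sample_id)
  pr <- rows[rows$gene_class == "PR", , drop = FALSE]
  if (any(is.na(pr$otu_id))) {
    warning("dropping ", sum(is.na(pr$otu_id)), " PR gene(s) without otu_id")
    pr <- pr[!is.na(pr$otu_id), , drop = FALSE]
  }
  cov <- gene_coverage(pr$count, pr$gene_length)
  total <- sum(cov)
  if (total <= 0) stop("degenerate normalizer: total PR coverage is zero in '",
                       sample_id, "'")
  shares <- vapply(split(cov, pr$otu_id), sum, 0) / total
  shares[order(names(shares))]
}
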