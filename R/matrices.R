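#' @useDynLib rhodoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues plus \code{X} for ambiguity.
#' @export
aa_alphabet <- function() "ACDEFGHIKLMNPQRSTVWYX"

#' Protein substitution matrix
#'
#' Builds a validated substitution matrix over the 20 standard amino acids
#' plus \code{X}. The default is BLOSUM62 (taken from \pkg{Biostrings}) with
#' every score involving \code{X} set to 0, so ambiguous residues are scored
#' neutrally rather than penalised.
#'
#' @param name matrix name; currently \code{"BLOSUM62"} or \code{"custom"}.
#' @param scores for \code{name = "custom"}, a symmetric numeric matrix with
#'   dimnames covering \code{aa_alphabet()}.
#' @return a numeric matrix of class \code{"substitution_matrix"} with a
#'   \code{name} attribute.
#' @examples
#' m <- substitution_matrix()
#' m["M", "M"]  # 5
#' @export
substitution_matrix <- function(name = "BLOSUM62", scores = NULL) {
  aa <- strsplit(aa_alphabet(), "")[[1]]
  if (identical(name, "BLOSUM62")) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    full <- env$BLOSUM62
    scores <- full[aa, aa]
    scores["X", ] <- 0
    scores[, "X"] <- 0
  } else if (is.null(scores)) {
    stop("a custom substitution matrix requires 'scores'")
  }
  scores <- as.matrix(scores)
  if (!all(aa %in% rownames(scores)) || !all(aa %in% colnames(scores)))
    stop("substitution matrix must define every residue in ", aa_alphabet())
  scores <- scores[aa, aa]
  if (!isTRUE(all.equal(scores, t(scores))))
    stop("substitution matrix must be symmetric")
  storage.mode(scores) <- "double"
  attr(scores, "name") <- name
  class(scores) <- c("substitution_matrix", class(scores))
  scores
}

# simple uniform matrix, used in examples/tests
uniform_matrix <- function(match = 4, mismatch = -4) {
  aa <- strsplit(aa_alphabet(), "")[[1]]
  m <- matrix(mismatch, 21, 21, dimnames = list(aa, aa))
  diag(m) <- match
  substitution_matrix("custom", m)
}
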