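#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq against log10 starting copies over a dilution
#' series (typically decade dilutions, 1e8 down to 1e2 copies):
#' \deqn{Cq = intercept + slope \cdot \log_{10}(copies).}
#' Amplification efficiency is \eqn{E = 10^{-1/slope} - 1}; a slope of
#' -3.3219 corresponds to perfect doubling (E = 100\%). A warning is issued
#' when the slope falls outside [-3.9, -3.0] (efficiency roughly outside
#' 80-115\%).
#'
#' @param points data.frame with columns \code{known_copies} (> 0) and
#'   \code{cq}; at least 3 points with distinct log10 copies.
#' @return object of class \code{"standard_curve"} with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{efficiency}, \code{points},
#'   and the underlying \code{lm} fit.
#' @examples
#' pts <- data.frame(known_copies = 10^(2:8), cq = 38 - 3.5 * (2:8))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  if (!all(c("known_copies", "cq") %in% names(points)))
    stop("standard curve points need columns 'known_copies' and 'cq'")
  if (any(points$known_copies <= 0)) stop("known_copies must be positive")
  x <- log10(points$known_copies)
  if (nrow(points) < 3L || length(unique(round(x, 10))) < 2L ||
      stats::sd(x) == 0)
    stop("invalid curve: need >= 3 dilution points with distinct log10 copies")
  if (length(unique(round(x, 10))) < 3L)
    stop("invalid curve: need >= 3 distinct log10 copy values")
  fit <- stats::lm(cq ~ x, data = data.frame(x = x, cq = points$cq))
  slope <- unname(stats::coef(fit)[2L]); intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) stop("invalid curve: non-negative slope (Cq must fall with template)")
  if (slope < -3.9 || slope > -3.0)
    warning(sprintf("standard-curve slope %.3f outside [-3.9, -3.0]; efficiency %.0f%%",
                    slope, 100 * (10^(-1 / slope) - 1)))
  # direct r^2: summary.lm warns on the (legitimate) noiseless case
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((points$cq - mean(points$cq))^2)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 points = points, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> Cq = %.4f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  r^2 = %.5f, efficiency = %.1f%%, %d dilution points\n",
              x$r_squared, 100 * x$efficiency, nrow(x$points)))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.standard_curve <- function(object, ...) {
  list(coefficients = coef(object), r_squared = object$r_squared,
       efficiency = object$efficiency, n_points = nrow(object$points))
}

#' Predicted Cq for a template amount
#' @param object a \code{standard_curve}.
#' @param copies positive copy numbers.
#' @param ... unused.
#' @export
predict.standard_curve <- function(object, copies, ...) {
  object$intercept + object$slope * log10(copies)
}

#' Back-calculate copy numbers from Cq replicates
#'
#' The point estimate inverts the standard curve at the mean Cq
#' (\code{copies = 10^((mean(cq) - intercept) / slope)}); the coefficient of
#' variation is computed from the per-replicate back-calculated copies.
#' Cq values outside [0, 60] trigger a suspect-value warning.
#'
#' @param curve a \code{\link{fit_standard_curve}} result.
#' @param cq_replicates numeric Cq values (typically a triplicate). \code{NA}
#'   replicates (below detection) are dropped; an all-\code{NA} input returns
#'   a missing measurement (\code{copies = NA}), never zero.
#' @param assay_id,sample_id optional labels carried through.
#' @return object of class \code{"qpcr_measurement"}: list with \code{copies},
#'   \code{copies_cv}, \code{cq_mean}, \code{n_replicates}, labels.
#' @export
quantify_copies <- function(curve, cq_replicates, assay_id = NA_character_,
                            sample_id = NA_character_) {
  stopifnot(inherits(curve, "standard_curve"))
  if (length(cq_replicates) == 0L) stop("invalid input: no Cq replicates")
  cq <- cq_replicates[!is.na(cq_replicates)]
  if (length(cq) == 0L)
    return(structure(list(assay_id = assay_id, sample_id = sample_id,
                          copies = NA_real_, copies_cv = NA_real_,
                          cq_mean = NA_real_, n_replicates = 0L,
                          below_detection = TRUE), class = "qpcr_measurement"))
  if (any(cq < 0 | cq > 60))
    warning("suspect Cq value outside [0, 60]")
  back <- 10^((cq - curve$intercept) / curve$slope)
  copies <- 10^((mean(cq) - curve$intercept) / curve$slope)
  cv <- if (length(back) > 1L) stats::sd(back) / mean(back) else 0
  structure(list(assay_id = assay_id, sample_id = sample_id, copies = copies,
                 copies_cv = cv, cq_mean = mean(cq),
                 n_replicates = length(cq), below_detection = FALSE),
            class = "qpcr_measurement")
}

#' @export
print.qpcr_measurement <- function(x, ...) {
  if (isTRUE(x$below_detection)) {
    cat(sprintf("<qpcr_measurement> %s / %s: below detection\n",
                x$assay_id, x$sample_id))
  } else {
    cat(sprintf("<qpcr_measurement> %s / %s: %.3g copies (CV %.1f%%, mean Cq %.2f, n=%d)\n",
                x$assay_id, x$sample_id, x$copies, 100 * x$copies_cv,
                x$cq_mean, x$n_replicates))
  }
  invisible(x)
}

#' Genome-copy-corrected relative abundance of PR-bearing bacteria
#'
#' Normalises proteorhodopsin gene copies to 16S rRNA gene copies assuming
#' 1.9 copies of 16S and 1 copy of the PR gene per genome:
#' \deqn{(PR / pr\_copies\_per\_genome) / (16S / ss16\_copies\_per\_genome).}
#' Values above 1 are flagged, never clamped. A below-detection PR measurement
#' propagates as \code{NA}.
#'
#' @param pr,ss16 \code{qpcr_measurement} objects for the PR assay and the 16S
#'   assay of the same sample.
#' @param ss16_copies_per_genome assumed 16S copies per genome (default 1.9).
#' @param pr_copies_per_genome assumed PR copies per genome (default 1).
#' @return list with \code{sample_id}, \code{fraction}, \code{flag_gt1}.
#' @export
pr_relative_abundance <- function(pr, ss16, ss16_copies_per_genome = 1.9,
                                  pr_copies_per_genome = 1.0) {
  if (ss16_copies_per_genome <= 0 || pr_copies_per_genome <= 0)
    stop("per-genome copy numbers must be positive")
  if (!is.na(pr$sample_id) && !is.na(ss16$sample_id) &&
      !identical(pr$sample_id, ss16$sample_id))
    stop("mismatch: PR and 16S measurements come from different samples")
  if (isTRUE(ss16$below_detection) || is.na(ss16$copies) || ss16$copies <= 0)
    stop("degenerate normalizer: no 16S copies to normalise against")
  if (isTRUE(pr$below_detection) || is.na(pr$copies))
    return(list(sample_id = pr$sample_id, fraction = NA_real_, flag_gt1 = FALSE))
  genomes <- ss16$copies / ss16_copies_per_genome
  frac <- (pr$copies / pr_copies_per_genome) / genomes
  list(sample_id = pr$sample_id, fraction = frac, flag_gt1 = frac > 1)
}
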