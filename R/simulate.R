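#' Synthetic proteorhodopsin reference panel
#'
#' Generates PR-like proteins by bounded random substitution of the bundled
#' annotated reference: the proton-pumping triad positions 97/101/108 are
#' never touched, position 105 is set to L or M (green) or Q (blue), and every
#' other position mutates independently with probability \code{sub_rate}.
#' Decoys are C-terminal fragments of the reference that lack the C-helix
#' region entirely (they start downstream of position 108), heavily mutated,
#' so they fail the curation screen's domain-coverage rule by construction.
#'
#' @param n_green,n_blue,n_decoys nonnegative counts.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param ref annotated reference (default: bundled synthetic reference).
#' @param sub_rate per-position substitution probability for PR-derived
#'   sequences (default 0.1).
#' @param decoy_sub_rate substitution rate for decoy fragments (default 0.15).
#' @return list with \code{panel} (named list of \code{protein_record}),
#'   \code{reference}, and \code{truth} (data.frame id, class, color, length).
#' @export
generate_reference_panel <- function(n_green, n_blue, n_decoys, seed,
                                     ref = pr_reference(), sub_rate = 0.1,
                                     decoy_sub_rate = 0.15) {
  stopifnot(n_green >= 0, n_blue >= 0, n_decoys >= 0)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  refseq <- strsplit(ref$record$sequence, "")[[1]]
  keep <- ref$key_positions[c("97", "101", "108")]
  pos105 <- ref$key_positions[["105"]]

  mutate_seq <- function(s, free_pos, rate) {
    hit <- free_pos[stats::runif(length(free_pos)) < rate]
    for (p in hit) s[p] <- sample(setdiff(aa, s[p]), 1L)
    s
  }
  free <- setdiff(seq_along(refseq), c(keep, pos105))

  make_pr <- function(id, color) {
    s <- mutate_seq(refseq, free, sub_rate)
    s[pos105] <- if (color == "green") sample(c("L", "M"), 1L) else "Q"
    protein_record(id, paste(s, collapse = ""))
  }
  helix_end <- max(ref$key_positions)
  frag_start <- helix_end + 23L   # well downstream of the C-helix region
  make_decoy <- function(id) {
    s <- refseq[frag_start:length(refseq)]
    s <- mutate_seq(s, seq_along(s), decoy_sub_rate)
    protein_record(id, paste(s, collapse = ""))
  }

  panel <- list(); truth <- NULL
  add <- function(rec, class, color) {
    panel[[rec$id]] <<- rec
    truth <<- rbind(truth, data.frame(id = rec$id, class = class, color = color,
                                      length = nchar(rec$sequence),
                                      stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_green)) add(make_pr(sprintf("green_PR_%02d", i), "green"),
                                  "PR", "green")
  for (i in seq_len(n_blue)) add(make_pr(sprintf("blue_PR_%02d", i), "blue"),
                                 "PR", "blue")
  for (i in seq_len(n_decoys)) add(make_decoy(sprintf("decoy_%02d", i)),
                                   "decoy", NA_character_)
  list(panel = panel, reference = ref, truth = truth)
}

#' Edit a protein at reference-numbered positions
#'
#' Maps the requested reference positions onto the record by global alignment
#' and substitutes the residues there; everything else is untouched. Used to
#' plant variants such as a lysine at position 108.
#'
#' @param record a \code{protein_record}.
#' @param ref an \code{annotated_reference}.
#' @param edits named character vector, e.g. \code{c("108" = "K")}.
#' @return the edited \code{protein_record}.
#' @export
mutate_positions <- function(record, ref, edits) {
  if (length(edits) == 0L) return(record)
  mapped <- map_reference_positions(record, ref, positions = names(edits))
  s <- strsplit(record$sequence, "")[[1]]
  for (p in names(edits)) {
    if (is.na(mapped[[p]]))
      stop("position ", p, " is unmappable in record '", record$id, "'")
    s[mapped[[p]]] <- edits[[p]]
  }
  protein_record(record$id, paste(s, collapse = ""),
                 taxon = record$taxon, source_sample = record$source_sample)
}

#' Ground-truth synthetic community specification
#'
#' Defines a mock bacterial community: every taxon carries exactly one copy of
#' each of the four single-copy housekeeping genes; PR-bearing taxa carry one
#' PR gene of known color plus the retinal biosynthesis genes blh, crtB and
#' crtY. Per-gene-class expression multipliers drive the transcript simulator.
#'
#' @param taxa data.frame with columns \code{taxon_id}, \code{abundance}
#'   (fractions summing to 1 within 1e-9), \code{has_pr} (logical),
#'   \code{pr_color} ("green"/"blue" for PR-bearers), \code{pr_multiplier}
#'   (PR expression multiplier, PR-bearers only).
#' @param multipliers named list of expression multipliers for the non-PR
#'   classes (housekeeping families, blh, crtB, crtY).
#' @param gene_lengths named vector of gene lengths in nt.
#' @return object of class \code{"community_spec"}.
#' @export
community_spec <- function(taxa,
                           multipliers = list("recA" = 1, "rplB" = 1,
                                              "rpoB" = 1, "EF-Tu" = 1,
                                              "blh" = 14 / 17, "crtB" = 0.7,
                                              "crtY" = 0.6),
                           gene_lengths = c(PR = 750, recA = 1065, rplB = 830,
                                            rpoB = 4100, "EF-Tu" = 1185,
                                            blh = 900, crtB = 930, crtY = 1150)) {
  req <- c("taxon_id", "abundance", "has_pr")
  if (!all(req %in% names(taxa))) stop("taxa needs columns ", paste(req, collapse = ", "))
  if (abs(sum(taxa$abundance) - 1) > 1e-9)
    stop("invalid spec: taxon abundances must sum to 1")
  if (!"pr_color" %in% names(taxa)) taxa$pr_color <- NA_character_
  if (!"pr_multiplier" %in% names(taxa)) taxa$pr_multiplier <- NA_real_
  bad <- taxa$has_pr & (is.na(taxa$pr_color) | !taxa$pr_color %in% c("green", "blue"))
  if (any(bad)) stop("PR-bearing taxa need pr_color green or blue")
  taxa$pr_multiplier[taxa$has_pr & is.na(taxa$pr_multiplier)] <- 1
  for (h in hk_families_dna())
    if (is.null(multipliers[[h]])) stop("missing multiplier for ", h)
  structure(list(taxa = taxa, multipliers = multipliers,
                 gene_lengths = gene_lengths),
            class = "community_spec")
}

#' Default demo community
#'
#' Ten taxa; three carry PR (green at abundances 0.05 and 0.07, blue at 0.05),
#' so the true PR-bearing fraction is 0.17 — the scale of the 2014 metagenome
#' estimate this package's estimator targets. Green PR genes dominate the DNA
#' (green share ~0.71) while the blue PR is transcribed far more strongly
#' (multiplier 30 vs 5), so blue PR dominates the transcript pool (~0.71) —
#' the "green-abundant DNA, blue-dominant RNA" regime. Retinal-gene
#' multipliers put PR:blh expression at exactly 15:1.
#'
#' @return a \code{\link{community_spec}}.
#' @export
default_community_spec <- function() {
  taxa <- data.frame(
    taxon_id = sprintf("taxon%02d", 1:10),
    abundance = c(0.07, 0.05, 0.05, 0.25, 0.18, 0.12, 0.10, 0.08, 0.06, 0.04),
    has_pr = c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
    pr_color = c("green", "green", "blue", rep(NA, 7)),
    pr_multiplier = c(5, 5, 30, rep(NA, 7)),
    stringsAsFactors = FALSE)
  community_spec(taxa)
}

#' Expand a community spec into a gene catalog with analytic truths
#'
#' @param spec a \code{\link{community_spec}}.
#' @return object of class \code{"pr_community"}: list with \code{catalog}
#'   (one row per gene: taxon_id, gene_id, gene_class, gene_length, color,
#'   otu_id, abundance, multiplier) and \code{truth} (analytic values derived
#'   from the spec without simulation: \code{pr_bearing_fraction},
#'   \code{green_gene_share}, \code{blue_transcript_fraction},
#'   \code{otu_shares}, \code{relative_expression} per gene class).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  taxa <- spec$taxa
  pr_taxa <- taxa[taxa$has_pr, , drop = FALSE]
  # one OTU per PR gene, labelled by descending DNA abundance
  pr_taxa <- pr_taxa[order(-pr_taxa$abundance, pr_taxa$taxon_id), , drop = FALSE]
  otu_of <- stats::setNames(sprintf("OTU%02d", seq_len(nrow(pr_taxa))),
                            pr_taxa$taxon_id)
  rows <- list()
  for (i in seq_len(nrow(taxa))) {
    t <- taxa[i, ]
    classes <- hk_families_dna()
    if (t$has_pr) classes <- c(classes, "PR", "blh", "crtB", "crtY")
    for (cl in classes) {
      mult <- if (cl == "PR") t$pr_multiplier else spec$multipliers[[cl]]
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = t$taxon_id,
        gene_id = paste0(t$taxon_id, "_", cl),
        gene_class = cl,
        gene_length = unname(spec$gene_lengths[[cl]]),
        color = if (cl == "PR") t$pr_color else NA_character_,
        otu_id = if (cl == "PR") unname(otu_of[t$taxon_id]) else NA_character_,
        abundance = t$abundance,
        multiplier = mult,
        stringsAsFactors = FALSE)
    }
  }
  catalog <- do.call(rbind, rows)

  pr_mass <- sum(pr_taxa$abundance)
  green <- pr_taxa$pr_color == "green"
  tr_mass <- pr_taxa$abundance * pr_taxa$pr_multiplier
  hk_expr <- mean(vapply(hk_families_rna(), function(h)
    sum(taxa$abundance * spec$multipliers[[h]]), 0))
  rel_expr <- c(PR = sum(tr_mass) / hk_expr,
                vapply(c("blh", "crtB", "crtY"), function(cl)
                  sum(pr_taxa$abundance * spec$multipliers[[cl]]) / hk_expr, 0))
  truth <- list(
    pr_bearing_fraction = pr_mass,
    green_gene_share = if (pr_mass > 0) sum(pr_taxa$abundance[green]) / pr_mass else NA,
    blue_transcript_fraction = if (sum(tr_mass) > 0)
      sum(tr_mass[!green]) / sum(tr_mass) else NA,
    otu_shares = if (pr_mass > 0)
      stats::setNames(pr_taxa$abundance / pr_mass, unname(otu_of[pr_taxa$taxon_id]))
      else numeric(0),
    relative_expression = rel_expr)
  structure(list(catalog = catalog, truth = truth, spec = spec),
            class = "pr_community")
}

#' @export
print.pr_community <- function(x, ...) {
  cat(sprintf("<pr_community> %d taxa, %d genes; true PR-bearing fraction %.3f\n",
              length(unique(x$catalog$taxon_id)), nrow(x$catalog),
              x$truth$pr_bearing_fraction))
  invisible(x)
}

.simulate_counts <- function(community, depth, seed, sample_id, use_multiplier) {
  stopifnot(inherits(community, "pr_community"), depth > 0)
  set.seed(seed)
  cat_ <- community$catalog
  lambda <- cat_$abundance * cat_$gene_length * depth *
    if (use_multiplier) cat_$multiplier else 1
  counts <- data.frame(sample_id = sample_id,
                       gene_id = cat_$gene_id,
                       gene_class = cat_$gene_class,
                       gene_length = cat_$gene_length,
                       count = stats::rpois(nrow(cat_), lambda),
                       otu_id = cat_$otu_id,
                       color = cat_$color,
                       stringsAsFactors = FALSE)
  list(sample_id = sample_id, counts = counts, truth = community$truth)
}

#' Simulate metagenomic read counts for a community
#'
#' Per-gene counts are independent Poisson with mean
#' \code{abundance * gene_length * depth}, so the expected length-normalised
#' coverage of every gene is \code{abundance * depth} — the model under which
#' the single-copy-gene ratio estimator is exactly unbiased in expectation.
#'
#' @param community a \code{\link{generate_community}} result.
#' @param depth sequencing depth scale (expected reads per nt of a gene
#'   carried at abundance 1).
#' @param seed integer seed.
#' @param sample_id label for the simulated sample.
#' @return list with \code{sample_id}, \code{counts} (a gene count table),
#'   \code{truth} (the community's analytic truths).
#' @export
simulate_gene_counts <- function(community, depth, seed, sample_id = "metaG") {
  .simulate_counts(community, depth, seed, sample_id, use_multiplier = FALSE)
}

#' Simulate metatranscriptomic counts for a community
#'
#' As \code{\link{simulate_gene_counts}}, with each gene's Poisson mean scaled
#' by its expression multiplier. The analytic truth for relative expression of
#' a class is (abundance-weighted multiplier mass of the class) / (mean
#' housekeeping multiplier mass).
#'
#' @inheritParams simulate_gene_counts
#' @export
simulate_transcript_counts <- function(community, depth, seed, sample_id = "metaT") {
  .simulate_counts(community, depth, seed, sample_id, use_multiplier = TRUE)
}

#' Simulate a qPCR run (standards plus samples)
#'
#' Standards are decade dilutions (1e8 down to 1e2 copies by default) on the
#' line \code{Cq = intercept + slope * log10(copies)} with Gaussian noise;
#' sample Cq replicates are drawn from the same line at each assay's true copy
#' number.
#'
#' @param true_copies named vector of true copies per assay, e.g.
#'   \code{c(SAR11_PR = 1e4, "16S" = 1.9e5)}.
#' @param slope,intercept standard-curve parameters (defaults -3.5 and 38).
#' @param noise_sd Gaussian Cq noise (cycles); 0 gives exact round trips.
#' @param n_replicates Cq replicates per sample assay (default triplicate).
#' @param seed integer seed.
#' @param sample_id sample label.
#' @param standard_decades log10 copies of the dilution series (default 8:2).
#' @return list with \code{standards} (assay_id, known_copies, cq) and
#'   \code{samples} (assay_id, sample_id, replicate, cq).
#' @export
simulate_qpcr_run <- function(true_copies, slope = -3.5, intercept = 38,
                              noise_sd = 0.15, n_replicates = 3, seed = 1,
                              sample_id = "station_A",
                              standard_decades = 8:2) {
  stopifnot(slope < 0, noise_sd >= 0, n_replicates >= 1)
  set.seed(seed)
  assays <- names(true_copies)
  if (is.null(assays)) stop("true_copies must be a named vector of assays")
  standards <- do.call(rbind, lapply(assays, function(a) {
    copies <- 10^standard_decades
    data.frame(assay_id = a, known_copies = copies,
               cq = intercept + slope * log10(copies) +
                 stats::rnorm(length(copies), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  samples <- do.call(rbind, lapply(assays, function(a) {
    data.frame(assay_id = a, sample_id = sample_id,
               replicate = seq_len(n_replicates),
               cq = intercept + slope * log10(true_copies[[a]]) +
                 stats::rnorm(n_replicates, 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  list(standards = standards, samples = samples)
}
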