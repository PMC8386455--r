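rna_table <- function(pr = 60, rplB = 20, rpoB = 20, eftu = 20, blh = NA,
                      sample = "t1") {
  rows <- data.frame(
    sample_id = sample,
    gene_id = c("pr1", "rplB1", "rpoB1", "eftu1"),
    gene_class = c("PR", "rplB", "rpoB", "EF-Tu"),
    gene_length = 100, count = c(pr, rplB, rpoB, eftu),
    stringsAsFactors = FALSE)
  if (!is.na(blh))
    rows <- rbind(rows, data.frame(sample_id = sample, gene_id = "blh1",
                                   gene_class = "blh", gene_length = 100,
                                   count = blh))
  read_gene_counts(rows)
}

test_that("relative expression is the ratio to mean housekeeping coverage", {
  expect_equal(transcript_relative_abundance(rna_table(20), "t1", "PR")$relative_expression,
               1.0)
  expect_equal(transcript_relative_abundance(rna_table(60), "t1", "PR")$relative_expression,
               3.0)
  # a blh planted at PR/15 yields a fold ratio of 15 (> 10)
  tab <- rna_table(pr = 60, blh = 4)
  e_pr <- transcript_relative_abundance(tab, "t1", "PR")
  e_blh <- transcript_relative_abundance(tab, "t1", "blh")
  expect_equal(gene_fold_ratio(e_pr, e_blh), 15)
  expect_gt(gene_fold_ratio(e_pr, e_blh), 10)
})

test_that("recA is rejected as an RNA normaliser and zero HK coverage errors", {
  expect_error(transcript_relative_abundance(rna_table(), "t1", "PR",
                                             hk_families = c("recA", "rplB")),
               "recA")
  expect_error(transcript_relative_abundance(rna_table(rplB = 0), "t1", "PR"),
               "degenerate normalizer")
  expect_error(transcript_relative_abundance(rna_table(), "t1", "nope"),
               "not found")
})

test_that("housekeeping self-normalisation averages to exactly one", {
  set.seed(12)
  tab <- rna_table(pr = 33, rplB = 17, rpoB = 41, eftu = 8)
  hk <- vapply(hk_families_rna(), function(h)
    transcript_relative_abundance(tab, "t1", h)$relative_expression, 0)
  expect_equal(mean(hk), 1.0)
})

test_that("every transcription statistic is depth-invariant", {
  comm <- generate_community(default_community_spec())
  sim <- simulate_transcript_counts(comm, depth = 1, seed = 4)
  tab <- sim$counts
  scaled <- tab; scaled$count <- scaled$count * 11L
  for (target in c("PR", "blh")) {
    expect_equal(transcript_relative_abundance(scaled, "metaT", target)$relative_expression,
                 transcript_relative_abundance(tab, "metaT", target)$relative_expression)
  }
  expect_equal(color_transcript_partition(scaled, "metaT")$blue_fraction,
               color_transcript_partition(tab, "metaT")$blue_fraction)
})

test_that("color partition splits colored PR coverage and reports unknown mass", {
  all_green <- read_gene_counts(data.frame(
    sample_id = "t1", gene_id = c("pr1", "pr2"), gene_class = "PR",
    gene_length = 100, count = c(10, 20), color = "green"))
  expect_equal(color_transcript_partition(all_green, "t1")$green_fraction, 1.0)

  mix <- read_gene_counts(data.frame(
    sample_id = "t1", gene_id = c("b1", "g1", "u1"), gene_class = "PR",
    gene_length = 100, count = c(6, 4, 5),
    color = c("blue", "green", "unknown")))
  p <- color_transcript_partition(mix, "t1")
  expect_equal(p$blue_fraction, 0.6)
  expect_equal(p$green_fraction, 0.4)
  expect_equal(p$unknown_mass, 0.05)   # excluded from the denominator

  uncolored <- read_gene_counts(data.frame(
    sample_id = "t1", gene_id = "u1", gene_class = "PR",
    gene_length = 100, count = 5, color = "unknown"))
  expect_error(color_transcript_partition(uncolored, "t1"), "degenerate partition")
})

test_that("fold ratios require a shared sample and positive denominator", {
  e1 <- list(sample_id = "a", target = "PR", relative_expression = 3.0)
  e2 <- list(sample_id = "a", target = "blh", relative_expression = 0.2)
  expect_equal(gene_fold_ratio(e1, e2), 15.0)
  expect_equal(gene_fold_ratio(e1, e1), 1.0)
  e3 <- list(sample_id = "b", target = "blh", relative_expression = 0.2)
  expect_error(gene_fold_ratio(e1, e3), "mismatch")
  e4 <- list(sample_id = "a", target = "blh", relative_expression = 0)
  expect_error(gene_fold_ratio(e1, e4), "degenerate")
})

test_that("blue transcripts can dominate while green genes dominate the DNA", {
  # green PR genes are ~4x the blue in DNA abundance, but the blue carrier
  # transcribes PR much more strongly
  taxa <- data.frame(
    taxon_id = c("greenA", "greenB", "blueC", "other"),
    abundance = c(0.10, 0.10, 0.05, 0.75),
    has_pr = c(TRUE, TRUE, TRUE, FALSE),
    pr_color = c("green", "green", "blue", NA),
    pr_multiplier = c(2, 2, 40, NA), stringsAsFactors = FALSE)
  comm <- generate_community(community_spec(taxa))
  expect_gt(comm$truth$green_gene_share, 0.5)
  expect_gt(comm$truth$blue_transcript_fraction, 0.5)
  dna <- simulate_gene_counts(comm, depth = 2, seed = 21)
  rna <- simulate_transcript_counts(comm, depth = 2, seed = 22)
  green_dna <- 1 - color_transcript_partition(dna$counts, "metaG")$blue_fraction
  expect_gt(green_dna, 0.5)
  expect_gt(color_transcript_partition(rna$counts, "metaT")$blue_fraction, 0.5)
})
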