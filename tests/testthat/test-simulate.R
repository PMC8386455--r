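test_that("panel generation is deterministic and matches its truth table", {
  g1 <- generate_reference_panel(2, 2, 2, seed = 7)
  g2 <- generate_reference_panel(2, 2, 2, seed = 7)
  expect_identical(lapply(g1$panel, `[[`, "sequence"),
                   lapply(g2$panel, `[[`, "sequence"))
  g3 <- generate_reference_panel(2, 2, 2, seed = 8)
  expect_false(identical(lapply(g1$panel, `[[`, "sequence"),
                         lapply(g3$panel, `[[`, "sequence")))

  ann <- annotate_proteins(g1$panel[g1$truth$id[g1$truth$class == "PR"]],
                           g1$reference)
  expect_equal(ann$color_call, g1$truth$color[g1$truth$class == "PR"])
  cur <- curate_candidates(g1$panel[g1$truth$id[g1$truth$class == "decoy"]],
                           g1$reference)
  expect_true(all(!cur$domain_region_covered))
})

test_that("position edits change exactly the requested residue", {
  gen <- generate_reference_panel(1, 0, 0, seed = 3)
  rec <- gen$panel[[1L]]
  k108 <- mutate_positions(rec, gen$reference, c("108" = "K"))
  ann <- annotate_proteins(k108, gen$reference)
  expect_equal(ann$pump_call, "non_canonical")
  expect_equal(ann$res108, "K")
  # only one position differs from the original
  d <- mapply(function(a, b) a != b,
              strsplit(rec$sequence, "")[[1]], strsplit(k108$sequence, "")[[1]])
  expect_equal(sum(d), 1L)
  expect_identical(mutate_positions(rec, gen$reference, character(0)), rec)
  frag <- protein_record("frag", substring(rec$sequence, 150))
  expect_error(mutate_positions(frag, gen$reference, c("97" = "A")), "unmappable")
})

test_that("community truths are analytic functions of the spec", {
  two <- community_spec(data.frame(taxon_id = c("a", "b"), abundance = c(0.5, 0.5),
                                   has_pr = c(TRUE, FALSE), pr_color = c("green", NA),
                                   pr_multiplier = c(1, NA)))
  expect_equal(generate_community(two)$truth$pr_bearing_fraction, 0.5)

  expect_equal(generate_community(default_community_spec())$truth$pr_bearing_fraction,
               0.17)

  solo <- community_spec(data.frame(taxon_id = "a", abundance = 1, has_pr = TRUE,
                                    pr_color = "blue", pr_multiplier = 1))
  expect_equal(generate_community(solo)$truth$pr_bearing_fraction, 1.0)

  expect_error(community_spec(data.frame(taxon_id = c("a", "b"),
                                         abundance = c(0.5, 0.6),
                                         has_pr = FALSE)),
               "sum to 1")
  expect_error(community_spec(data.frame(taxon_id = "a", abundance = 1,
                                         has_pr = TRUE)),
               "pr_color")
})

test_that("the community catalog respects the one-copy gene complements", {
  comm <- generate_community(default_community_spec())
  per_taxon <- split(comm$catalog$gene_class, comm$catalog$taxon_id)
  for (t in names(per_taxon)) {
    expect_true(all(hk_families_dna() %in% per_taxon[[t]]))
    expect_lte(sum(per_taxon[[t]] == "PR"), 1L)
  }
  expect_equal(sum(comm$catalog$gene_class == "PR"), 3L)
  expect_equal(sort(unique(comm$catalog$otu_id[comm$catalog$gene_class == "PR"])),
               c("OTU01", "OTU02", "OTU03"))
})

test_that("count simulation is seeded and converges to the analytic truth", {
  comm <- generate_community(default_community_spec())
  s1 <- simulate_gene_counts(comm, depth = 1, seed = 5)
  s2 <- simulate_gene_counts(comm, depth = 1, seed = 5)
  expect_identical(s1$counts, s2$counts)

  # law of large numbers: at high depth the estimate approaches 0.17 within 1%
  deep <- simulate_gene_counts(comm, depth = 200, seed = 6)
  est <- pr_bearing_fraction(deep$counts, "metaG")$pr_fraction
  expect_lt(abs(est - 0.17) / 0.17, 0.01)

  deep_rna <- simulate_transcript_counts(comm, depth = 200, seed = 7)
  est_pr <- transcript_relative_abundance(deep_rna$counts, "metaT", "PR")$relative_expression
  expect_lt(abs(est_pr - comm$truth$relative_expression[["PR"]]) /
              comm$truth$relative_expression[["PR"]], 0.02)
})

test_that("uniform expression multipliers give unit relative expression", {
  taxa <- default_community_spec()$taxa
  taxa$pr_multiplier[taxa$has_pr] <- 1
  mult1 <- list("recA" = 1, "rplB" = 1, "rpoB" = 1, "EF-Tu" = 1,
                blh = 1, crtB = 1, crtY = 1)
  comm <- generate_community(community_spec(taxa, multipliers = mult1))
  expect_equal(unname(comm$truth$relative_expression[["PR"]]), 0.17)  # = abundance mass
  deep <- simulate_transcript_counts(comm, depth = 100, seed = 9)
  hk <- vapply(hk_families_rna(), function(h)
    transcript_relative_abundance(deep$counts, "metaT", h)$relative_expression, 0)
  expect_equal(mean(hk), 1.0)
})

test_that("simulated tables round-trip through the package readers", {
  comm <- generate_community(default_community_spec())
  sim <- simulate_gene_counts(comm, depth = 1, seed = 10)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(sim$counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_gene_counts(path)
  expect_equal(back, sim$counts)

  gen <- generate_reference_panel(2, 1, 1, seed = 11)
  fa <- tempfile(fileext = ".faa")
  write_proteins(gen$panel, fa)
  back_fa <- read_proteins(fa)
  expect_equal(lapply(back_fa, `[[`, "sequence"),
               lapply(gen$panel, `[[`, "sequence"))
})

test_that("simulated qPCR runs are seeded and honour the noise model", {
  r1 <- simulate_qpcr_run(c(PR = 1e4, "16S" = 1.9e5), seed = 3)
  r2 <- simulate_qpcr_run(c(PR = 1e4, "16S" = 1.9e5), seed = 3)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$standards), 14L)   # 7 decades x 2 assays
  expect_equal(nrow(r1$samples), 6L)      # triplicate x 2 assays

  exact <- simulate_qpcr_run(c(PR = 123), noise_sd = 0, seed = 4)
  expect_equal(exact$samples$cq, rep(38 - 3.5 * log10(123), 3))
  expect_error(simulate_qpcr_run(c(1e4), seed = 1), "named")
})
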