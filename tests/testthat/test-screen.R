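test_that("internal panel search reports best local hits deterministically", {
  set.seed(31)
  gen <- generate_reference_panel(2, 1, 0, seed = 31)
  panel <- gen$panel
  q <- panel[["green_PR_01"]]
  hits <- search_candidates(list(q), panel)
  expect_equal(hits$best_hit_id, "green_PR_01")
  self_score <- local_align(q, q)$score
  expect_equal(hits$score, self_score)

  # ties are broken by the lexicographically smaller hit id
  twin_panel <- list(protein_record("bbb", q$sequence),
                     protein_record("aaa", q$sequence))
  expect_equal(search_candidates(list(q), twin_panel)$best_hit_id, "aaa")

  # a featureless all-G 120-mer scores below the threshold and is dropped
  allg <- protein_record("allG", strrep("G", 120))
  expect_equal(nrow(search_candidates(list(allg), panel,
                                      screen_config(min_bitlike_score = 50))), 0L)
  expect_error(search_candidates(list(q), list()), "empty reference panel")
})

test_that("external hit import filters by E value and picks best row per query", {
  tab <- data.frame(
    query_id = c("q1", "q2", "q3", "q3"),
    subject_id = c("s1", "s2", "s3", "s4"),
    evalue = c(1e-8, 1e-6, 1e-9, 1e-12),
    bitscore = c(200, 100, 150, 180))
  out <- import_external_hits(tab)
  expect_true("q1" %in% out$query_id)        # 1e-8 <= 1e-7: retained
  expect_false("q2" %in% out$query_id)       # 1e-6 > 1e-7: dropped
  expect_equal(out$best_hit_id[out$query_id == "q3"], "s4")  # lowest evalue wins

  # outfmt-6 column names are accepted
  tab6 <- data.frame(qseqid = "q1", sseqid = "s1", evalue = 1e-8, bitscore = 5)
  expect_equal(import_external_hits(tab6)$query_id, "q1")

  expect_error(import_external_hits(data.frame(query_id = "q", evalue = 1)),
               "missing column 'subject_id'")
  bad <- data.frame(query_id = c("a", "b"), subject_id = c("s", "s"),
                    evalue = c("1e-9", "oops"), bitscore = c(1, 2))
  expect_error(import_external_hits(bad), "line 3")
})

test_that("curation applies the length and C-helix coverage rules", {
  ref <- pr_reference()
  # 99-aa fragment containing the full C-helix region: fails only on length
  frag99 <- protein_record("frag99", substring(ref$record$sequence, 60, 158))
  r <- curate_candidates(list(frag99), ref)
  expect_true(r$domain_region_covered)
  expect_false(r$passed_length)
  expect_false(r$retained)
  expect_match(r$reason, "length")

  # a full-length near-copy is retained
  full <- protein_record("full", ref$record$sequence)
  expect_true(curate_candidates(list(full), ref)$retained)

  # a boundary-length protein (exactly 100 aa) still fails: strictly > 100
  frag100 <- protein_record("frag100", substring(ref$record$sequence, 60, 159))
  expect_false(curate_candidates(list(frag100), ref)$retained)

  # triad identity is not a curation criterion: the K108 variant stays in
  k108 <- mutate_positions(full, ref, c("108" = "K"))
  expect_true(curate_candidates(list(k108), ref)$retained)
})

test_that("curation is monotone in length and separates PR from decoys", {
  set.seed(77)
  gen <- generate_reference_panel(4, 3, 5, seed = 77)
  res <- curate_candidates(gen$panel, gen$reference)
  truth <- gen$truth
  expect_setequal(res$query_id[res$retained],
                  truth$id[truth$class == "PR" & truth$length > 100])
  expect_true(all(!res$domain_region_covered[match(
    truth$id[truth$class == "decoy"], res$query_id)]))

  # truncating a retained protein below the length threshold flips retention
  kept <- gen$panel[[res$query_id[res$retained][1L]]]
  short <- protein_record(kept$id, substring(kept$sequence, 1, 99))
  expect_false(curate_candidates(list(short), gen$reference)$retained)
})

test_that("external hits and the internal search give the same retained set", {
  set.seed(13)
  gen <- generate_reference_panel(3, 2, 3, seed = 13)
  cfg <- screen_config(min_bitlike_score = 50)
  internal <- search_candidates(gen$panel, gen$panel, cfg)
  # fabricate an external table equivalent to the internal panel search
  ext <- data.frame(query_id = internal$query_id,
                    subject_id = internal$best_hit_id,
                    evalue = 1e-20, bitscore = internal$score)
  imported <- import_external_hits(ext, cfg)
  keep_int <- curate_candidates(gen$panel[internal$query_id], gen$reference, cfg)
  keep_ext <- curate_candidates(gen$panel[imported$query_id], gen$reference, cfg)
  expect_setequal(keep_int$query_id[keep_int$retained],
                  keep_ext$query_id[keep_ext$retained])
})
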