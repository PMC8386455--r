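test_that("global alignment reproduces known scores", {
  expect_equal(global_align("MKT", "MKT")$score, 15)  # 5 + 5 + 5 on the diagonal
  # frozen from the exhaustive-enumeration oracle over all alignments of 3-mers
  a <- global_align("MKT", "MRT")
  expect_equal(a$score, 12)                           # M:M 5, K:R 2, T:T 5
  expect_equal(a$aligned_query, "MKT")
  expect_equal(a$aligned_target, "MRT")
  expect_equal(enum_global("MKT", "MRT"), 12)

  m <- substitution_matrix("custom", {
    aa <- strsplit(aa_alphabet(), "")[[1]]
    x <- matrix(-4, 21, 21, dimnames = list(aa, aa)); diag(x) <- 4; x
  })
  a2 <- global_align("AC", "AGC", matrix = m, gap_open = 6, gap_extend = 1)
  expect_equal(a2$score, 2)                            # 4 + 4 - 6, frozen from oracle
  expect_equal(a2$aligned_query, "A-C")
  expect_equal(a2$aligned_target, "AGC")
  expect_equal(enum_global("AC", "AGC", m, 6, 1), 2)
})

test_that("local alignment finds embedded matches and floors at zero", {
  l <- local_align("MKT", "QQMKTQQ")
  expect_equal(l$score, 15)
  expect_equal(unname(l$query_span), c(1L, 3L))
  expect_equal(unname(l$target_span), c(3L, 5L))
  expect_equal(enum_local("MKT", "QQMKTQQ"), 15)

  neg <- local_align("WWW", "GGG")  # W:G = -2, no positive cell
  expect_equal(neg$score, 0)
  expect_equal(neg$aligned_query, "")
  expect_true(all(is.na(neg$query_span)))

  s <- "PRTEIN"
  self <- local_align(s, s)
  diag_sum <- sum(vapply(strsplit(s, "")[[1]],
                         function(ch) substitution_matrix()[ch, ch], 0))
  expect_equal(self$score, diag_sum)
})

test_that("DP scores match the exhaustive-enumeration oracle on random short pairs", {
  set.seed(11)
  for (i in 1:40) {
    a <- rand_seq(sample(1:8, 1)); b <- rand_seq(sample(1:8, 1))
    expect_equal(global_align(a, b)$score, enum_global(a, b),
                 info = paste(a, b, "global"))
    expect_equal(local_align(a, b)$score, enum_local(a, b),
                 info = paste(a, b, "local"))
  }
})

test_that("scores agree with an independent aligner on longer random pairs", {
  # Biostrings charges gapOpening + L * gapExtension per gap of length L, so
  # its opening penalty is our gap_open - gap_extend
  set.seed(23)
  bl62 <- substitution_matrix()
  for (i in 1:10) {
    a <- rand_seq(sample(30:80, 1)); b <- rand_seq(sample(30:80, 1))
    pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                        Biostrings::AAString(b),
                                        substitutionMatrix = unclass(bl62),
                                        gapOpening = 10, gapExtension = 1,
                                        type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b)$score, pa)
    pl <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                        Biostrings::AAString(b),
                                        substitutionMatrix = unclass(bl62),
                                        gapOpening = 10, gapExtension = 1,
                                        type = "local", scoreOnly = TRUE)
    expect_equal(local_align(a, b)$score, max(pl, 0))
  }
})

test_that("alignment invariants hold: symmetry, rescoring, gap structure, spans", {
  set.seed(5)
  for (i in 1:15) {
    a <- rand_seq(sample(5:40, 1)); b <- rand_seq(sample(5:40, 1))
    g <- global_align(a, b); l <- local_align(a, b)
    expect_equal(g$score, global_align(b, a)$score)
    expect_equal(l$score, local_align(b, a)$score)
    expect_gte(l$score, 0)
    for (aln in list(g, l)) {
      qa <- strsplit(aln$aligned_query, "")[[1]]
      qt <- strsplit(aln$aligned_target, "")[[1]]
      expect_equal(length(qa), length(qt))
      expect_false(any(qa == "-" & qt == "-"))
      expect_equal(alignment_score(aln), aln$score)
      if (nzchar(aln$aligned_query)) {
        expect_equal(paste(qa[qa != "-"], collapse = ""),
                     substring(a, aln$query_span[1], aln$query_span[2]))
        expect_equal(paste(qt[qt != "-"], collapse = ""),
                     substring(b, aln$target_span[1], aln$target_span[2]))
      }
    }
  }
})

test_that("percent identity supports both denominator conventions", {
  ten <- rand_seq(10)
  expect_equal(percent_identity(global_align(ten, ten)), 1.0)
  expect_equal(percent_identity(global_align(ten, ten), "alignment_columns"), 1.0)
  expect_equal(percent_identity(global_align("AAAA", "AAAT")), 0.75)
  # 4 matched residues: 4/4 under shorter_seq, 4/6 over the forced 6 columns
  a <- global_align("AAAA", "AAAAAA")
  expect_equal(sum(strsplit(a$aligned_query, "")[[1]] ==
                     strsplit(a$aligned_target, "")[[1]]), 4)
  expect_equal(percent_identity(a, "shorter_seq"), 1.0)
  expect_equal(percent_identity(a, "alignment_columns"), 4 / 6)
  # an empty local alignment has zero matches, and zero columns to divide by
  empty <- local_align("WWW", "GGG")
  expect_equal(percent_identity(empty, "shorter_seq"), 0)
  expect_error(percent_identity(empty, "alignment_columns"), "undefined identity")
})

test_that("input validation: empty sequences, bad characters, gap penalties, case", {
  expect_error(global_align("", "MKT"), "empty")
  expect_error(global_align("MKT", "MKB"), "invalid character 'B'")
  expect_error(global_align("MKT", "MKT", gap_open = 1, gap_extend = 2),
               "gap_open >= gap_extend")
  expect_equal(global_align("mkt", "MKT")$score, 15)
  expect_warning(r <- protein_record("p1", "MKT*"), "stop character")
  expect_equal(r$sequence, "MKT")
  # X is scored 0 against anything by default
  expect_equal(global_align("XXX", "MKT")$score, 0)
})
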