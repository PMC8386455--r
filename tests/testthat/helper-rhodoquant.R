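# shared fixtures and independent oracles for the test suite

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# substitute a fraction of positions, never producing the same residue
mutate_rate <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  for (p in hit) s[p] <- sample(setdiff(AA20, s[p]), 1L)
  paste(s, collapse = "")
}

# exhaustive-score oracles (recursion over edit paths, independent of the DP)
enum_global <- function(a, b, matrix = substitution_matrix(), open = 11, ext = 1)
  rhodoquant:::.enum_global_score_cpp(a, b, unclass(matrix), aa_alphabet(), open, ext)

enum_local <- function(a, b, matrix = substitution_matrix(), open = 11, ext = 1)
  rhodoquant:::.enum_local_score_cpp(a, b, unclass(matrix), aa_alphabet(), open, ext)

# independent reimplementation of the greedy clustering rule: sort by length
# (desc, ties by id), assign each record to the first representative in
# founding order at >= threshold identity, else found a new cluster
brute_force_clusters <- function(records, threshold = 0.82) {
  ids <- vapply(records, function(r) r$id, "")
  lens <- vapply(records, function(r) nchar(r$sequence), 0L)
  records <- records[order(-lens, ids)]
  reps <- list(); membership <- character(0)
  for (rec in records) {
    rep_id <- NA_character_
    for (r in reps) {
      idn <- percent_identity(global_align(rec, r), "shorter_seq")
      if (idn >= threshold) { rep_id <- r$id; break }
    }
    if (is.na(rep_id)) { reps[[length(reps) + 1L]] <- rec; rep_id <- rec$id }
    membership[rec$id] <- rep_id
  }
  membership
}

# partition as a canonical set of sorted member-id groups (label-free)
partition_of <- function(membership) {
  unname(lapply(split(names(membership), membership), sort))
}
canon_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, "", 1L))]
}

# structured sequence families whose pairwise identities straddle 0.82
clustery_records <- function(n_families = 5, per_family = 6, len_range = c(120, 250)) {
  recs <- list(); k <- 0
  for (f in seq_len(n_families)) {
    base <- rand_seq(sample(len_range[1]:len_range[2], 1L))
    for (j in seq_len(per_family)) {
      k <- k + 1
      recs[[k]] <- protein_record(sprintf("seq%03d", k),
                                  mutate_rate(base, runif(1, 0.02, 0.45)))
    }
  }
  recs
}

make_count_table <- function(...) read_gene_counts(data.frame(...))

# a community spec with a prescribed true PR-bearing fraction, keeping the
# default demo community's internal proportions
community_with_fraction <- function(frac) {
  spec <- default_community_spec()
  taxa <- spec$taxa
  pr <- taxa$has_pr
  taxa$abundance[pr] <- taxa$abundance[pr] / sum(taxa$abundance[pr]) * frac
  taxa$abundance[!pr] <- taxa$abundance[!pr] / sum(taxa$abundance[!pr]) * (1 - frac)
  community_spec(taxa)
}
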