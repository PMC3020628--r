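test_that("read_alignment accepts well-formed input and rejects ragged, unmapped and illegal records", {
  dir <- withr::local_tempdir()
  ids <- c("s1", "s2", "s3")
  seqs <- c("ACGTACGTAA", "ACGTACGTAT", "ACGTACGTAC")
  fa <- write_fasta_file(seqs, ids, file.path(dir, "aln.fasta"))
  st <- write_sample_table(ids, c("L1", "L1", "L2"), file.path(dir, "samples.tsv"))

  aln <- read_alignment(fa, st, "COI")
  expect_s3_class(aln, "labeled_alignment")
  expect_equal(aln$length, 10)
  expect_equal(length(aln$sample_ids), 3)
  expect_equal(unname(aln$locality_of["s3"]), "L2")

  ragged <- write_fasta_file(c("ACGTACGTAA", "ACGTACGTA"), c("s1", "s2"),
                             file.path(dir, "ragged.fasta"))
  st2 <- write_sample_table(c("s1", "s2"), c("L1", "L1"),
                            file.path(dir, "samples2.tsv"))
  expect_error(read_alignment(ragged, st2, "COI"),
               class = "kelp_alignment_error")

  fa4 <- write_fasta_file(c(seqs, "ACGTACGTAG"), c(ids, "s4"),
                          file.path(dir, "four.fasta"))
  expect_error(read_alignment(fa4, st, "COI"), class = "kelp_mapping_error")

  expect_error(labeled_alignment("COI", "s1", "ACGTZ",
                                 c(s1 = "L1")),
               class = "kelp_format_error")
  expect_error(labeled_alignment("COI", character(0), character(0),
                                 character(0)),
               class = "kelp_empty_input_error")
})

test_that("collapse_haplotypes groups identical sequences with rank-based deterministic ids", {
  ht <- make_ht(c("AAA", "AAA", "AAT", "AAT", "AAT"),
                c("L1", "L1", "L1", "L2", "L2"))
  expect_equal(length(ht$haplotype_ids), 2)
  # most frequent haplotype (AAT, 3 copies) is ranked first
  expect_equal(unname(ht$haplotype_seqs[["H1"]]), "AAT")
  expect_equal(ht$counts["L1", ], c(H1 = 1L, H2 = 2L))
  expect_equal(ht$counts["L2", ], c(H1 = 2L, H2 = 0L))
  expect_equal(sum(ht$counts), 5)

  # all-identical input: one haplotype, counts = per-locality sample sizes
  ht1 <- make_ht(rep("ACGT", 4), c("A", "A", "B", "A"))
  expect_equal(length(ht1$haplotype_ids), 1)
  expect_equal(unname(ht1$counts[, "H1"]), c(3L, 1L))

  # frequency ties broken by first occurrence order
  ht2 <- make_ht(c("TTT", "CCC", "TTT", "CCC"), rep("L1", 4))
  expect_equal(unname(ht2$haplotype_seqs), c("TTT", "CCC"))
})

test_that("collapsing is idempotent and order-invariant in membership and counts", {
  withr::local_seed(42)
  for (rep in 1:5) {
    seqs <- sample(c("AAAA", "AATA", "CGTA", "AAAA", "AATA", "AAAA"), 12,
                   replace = TRUE)
    locs <- sample(c("L1", "L2", "L3"), 12, replace = TRUE)
    ht <- make_ht(seqs, locs)

    # idempotence: collapsing the haplotype sequences reproduces them
    ht2 <- make_ht(unname(ht$haplotype_seqs),
                   rep("X", length(ht$haplotype_ids)))
    expect_setequal(unname(ht2$haplotype_seqs), unname(ht$haplotype_seqs))
    expect_true(all(colSums(ht2$counts) == 1))

    # permuting record order: same counts per (locality, sequence)
    perm <- sample(length(seqs))
    htp <- make_ht(seqs[perm], locs[perm])
    expect_setequal(unname(htp$haplotype_seqs), unname(ht$haplotype_seqs))
    by_seq <- ht$counts[, match(unname(htp$haplotype_seqs),
                                unname(ht$haplotype_seqs)), drop = FALSE]
    expect_equal(unname(by_seq[rownames(htp$counts), ]),
                 unname(htp$counts))
  }
})

test_that("site_summary finds variable sites, classes and codon positions", {
  # T<->A at position 4: transversion
  ss <- site_summary(make_ht(c("ACGT", "ACGA"), c("L1", "L2")))
  expect_equal(ss$variable_positions, 4)
  expect_equal(unname(ss$substitution_class_of), "transversion")

  # G<->A at position 3: transition; frame offset shifts codon position
  ss2 <- site_summary(make_ht(c("ACGT", "ACAT"), c("L1", "L2")))
  expect_equal(ss2$variable_positions, 3)
  expect_equal(unname(ss2$substitution_class_of), "transition")
  expect_equal(unname(ss2$codon_position_of), 3)
  ss2b <- site_summary(make_ht(c("ACGT", "ACAT"), c("L1", "L2")),
                       frame_offset = 1)
  expect_equal(unname(ss2b$codon_position_of), 1)

  # three bases at one site: complex
  ss3 <- site_summary(make_ht(c("ACGT", "ATGT", "AGGT"),
                              c("L1", "L2", "L3")))
  expect_equal(unname(ss3$substitution_class_of), "complex")

  # ambiguity or gap anywhere at a position excludes it
  ss4 <- site_summary(make_ht(c("ANGT", "ATG-", "ATGT"),
                              c("L1", "L2", "L3")))
  expect_equal(ss4$n_variable, 0)

  # fewer than two haplotypes: warning + empty summary, not failure
  expect_warning(ss5 <- site_summary(make_ht(c("ACGT", "ACGT"),
                                             c("L1", "L2"))),
                 class = "kelp_warning")
  expect_equal(ss5$n_variable, 0)
})

test_that("two 886 bp haplotypes differing at 12 sites give 12 variable sites", {
  withr::local_seed(886)
  pair <- seq_pair_with_diffs(886, 12)
  ss <- site_summary(make_ht(pair, c("north", "south"), gene = "rbcL"))
  expect_equal(ss$n_variable, 12)
})

test_that("variable-site count is identical on the alignment and on its haplotype table", {
  withr::local_seed(7)
  for (rep in 1:5) {
    base <- rand_seq(40)
    pool <- c(base, mutate_sequence(base, 2), mutate_sequence(base, 4))
    seqs <- sample(pool, 15, replace = TRUE)
    ht <- make_ht(seqs, rep("L1", 15))
    ss <- site_summary(ht)
    # direct computation on the full alignment, duplicates retained
    m <- do.call(rbind, strsplit(seqs, ""))
    n_var_full <- sum(apply(m, 2, function(col) {
      all(col %in% c("A", "C", "G", "T")) && length(unique(col)) >= 2
    }))
    expect_equal(ss$n_variable, n_var_full)
  }
})

test_that("haplotypes can be renamed through a sidecar map", {
  ht <- make_ht(c("AAT", "AAT", "CCT"), c("L1", "L2", "L2"))
  ht2 <- rename_haplotypes(ht, c(H1 = "C-I", H2 = "C-II"))
  expect_equal(ht2$haplotype_ids, c("C-I", "C-II"))
  expect_equal(colnames(ht2$counts), c("C-I", "C-II"))
  expect_error(rename_haplotypes(ht, c(H1 = "A")),
               class = "kelp_mapping_error")
})
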