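test_that("raw_differences counts differing unambiguous sites only", {
  expect_equal(raw_differences("ACGT", "ACGT"), 0)
  expect_equal(raw_differences("ACGT", "ACGA"), 1)
  # position 3 excluded by the N, position 4 differs
  expect_equal(raw_differences("ACNT", "ACGA"), 1)
  expect_equal(raw_differences("AC-T", "ACGT"), 0)
  expect_error(raw_differences("ACGT", "ACG"),
               class = "kelp_alignment_error")
})

test_that("p_distance is raw differences over comparable sites", {
  withr::local_seed(12)
  pair <- seq_pair_with_diffs(886, 12)
  expect_equal(p_distance(pair[1], pair[2]), 12 / 886)
  expect_equal(round_half_up(100 * p_distance(pair[1], pair[2]), 1), 1.4)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "TTTT"), 1)
  expect_error(p_distance("NNNN", "ACGT"),
               class = "kelp_undefined_distance_error")
})

test_that("Nei's raw D matches direct enumeration over all sample pairs", {
  h1 <- "AACCGGTT"
  h2 <- "AATCGGTA"  # 2 steps from h1
  expect_equal(nei_average_pairwise_D(c(h1), c(h1)), 0)
  expect_equal(nei_average_pairwise_D(c(h1, h1), c(h2, h2)), 2)
  # frozen from the pair-enumeration oracle: (2 + 2 + 0) / 3
  expect_equal(nei_average_pairwise_D(c(h1, h1, h2), c(h2)), 4 / 3)
  expect_equal(oracle_D(c(h1, h1, h2), c(h2)), 4 / 3)
  expect_error(nei_average_pairwise_D(character(0), c(h1)),
               class = "kelp_empty_input_error")

  withr::local_seed(99)
  base <- rand_seq(30)
  pool <- c(base, mutate_sequence(base, 1), mutate_sequence(base, 3),
            mutate_sequence(base, 5))
  for (rep in 1:10) {
    pa <- sample(pool, sample(1:6, 1), replace = TRUE)
    pb <- sample(pool, sample(1:6, 1), replace = TRUE)
    expect_equal(nei_average_pairwise_D(pa, pb), oracle_D(pa, pb))
  }
})

test_that("D reduces to raw differences for singletons and is duplication-invariant", {
  withr::local_seed(5)
  for (rep in 1:5) {
    pair <- seq_pair_with_diffs(50, sample(0:6, 1))
    expect_equal(nei_average_pairwise_D(pair[1], pair[2]),
                 raw_differences(pair[1], pair[2]))
    base <- rand_seq(30)
    pa <- c(base, mutate_sequence(base, 2))
    pb <- c(base, mutate_sequence(base, 4), mutate_sequence(base, 1))
    d1 <- nei_average_pairwise_D(pa, pb)
    # duplicating every member of a population leaves D unchanged
    expect_equal(nei_average_pairwise_D(rep(pa, 3), pb), d1)
    expect_equal(nei_average_pairwise_D(pa, rep(pb, 2)), d1)
    expect_true(d1 <= max(outer(pa, pb, Vectorize(raw_differences))))
  }
})

test_that("pairwise FST matches exhaustive pair enumeration and handles fixation", {
  h1 <- "AAAAGGGG"
  h2 <- mutate_sequence(h1, 4)
  # two populations fixed for different haplotypes: FST = 1
  f <- pairwise_fst(rep(h1, 5), rep(h2, 4))
  expect_equal(f$fst, 1)
  expect_true(f$defined)
  # same fixed haplotype: pi_between = 0, FST undefined
  f0 <- pairwise_fst(rep(h1, 3), rep(h1, 3))
  expect_false(f0$defined)
  expect_true(is.na(f0$fst))
  expect_equal(f0$pi_between, 0)

  # frozen from the oracle: pop_a={h1,h2}, pop_b={h2,h2}
  # pi_between = (4+0+4+0)/4 = 2, pi_within = (4 + 0)/2 = 2 -> FST = 0
  fd <- pairwise_fst(c(h1, h2), c(h2, h2))
  expect_equal(fd$pi_between, 2)
  expect_equal(fd$pi_within_a, 4)
  expect_equal(fd$pi_within_b, 0)
  expect_equal(fd$fst, 0)
  expect_equal(oracle_fst(c(h1, h2), c(h2, h2)), 0)

  # identical polymorphic populations: FST ~ 0; random cases match oracle
  withr::local_seed(11)
  base <- rand_seq(40)
  pool <- c(base, mutate_sequence(base, 2), mutate_sequence(base, 6))
  mix <- sample(pool, 12, replace = TRUE)
  fm <- pairwise_fst(mix, mix)
  if (fm$defined) expect_lt(fm$fst, 0.15)
  for (rep in 1:8) {
    pa <- sample(pool, sample(2:6, 1), replace = TRUE)
    pb <- sample(pool, sample(2:6, 1), replace = TRUE)
    f <- pairwise_fst(pa, pb)
    o <- oracle_fst(pa, pb)
    if (is.na(o)) {
      expect_false(f$defined)
    } else {
      expect_equal(f$fst, o)
      expect_gte(f$fst, 0)
      expect_lte(f$fst, 1)
    }
  }
})

test_that("population D matrix equals the per-cell enumeration oracle", {
  withr::local_seed(21)
  base <- rand_seq(25)
  pool <- c(base, mutate_sequence(base, 1), mutate_sequence(base, 3),
            mutate_sequence(base, 7))
  seqs <- sample(pool, 18, replace = TRUE)
  locs <- sample(c("L1", "L2", "L3"), 18, replace = TRUE)
  ht <- make_ht(seqs, locs)
  D <- population_distance_matrix(ht)
  for (a in rownames(D)) for (b in rownames(D)) {
    if (a == b) {
      expect_equal(unname(D[a, a]), 0)
    } else {
      expect_equal(unname(D[a, b]), oracle_D(seqs[locs == a], seqs[locs == b]))
    }
  }
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)

  # all localities fixed for one haplotype: zero matrix
  ht0 <- make_ht(rep("ACGT", 6), rep(c("A", "B", "C"), 2))
  expect_true(all(population_distance_matrix(ht0) == 0))
})

test_that("coastal distance matrix is |position difference| and enforces ordering", {
  lt <- data.frame(locality = c("A", "B", "C"), order_index = 1:3,
                   coastal_position_km = c(0, 10, 25))
  m <- coastal_distance_matrix(lt)
  expect_equal(unname(m["A", "B"]), 10)
  expect_equal(unname(m["A", "C"]), 25)
  expect_equal(unname(m["B", "C"]), 15)
  # reversing input row order leaves the labeled matrix unchanged
  m2 <- coastal_distance_matrix(lt[3:1, ])
  expect_equal(unclass(m2)[rownames(m), colnames(m)], unclass(m),
               ignore_attr = TRUE)
  bad <- data.frame(locality = c("A", "B"), order_index = 1:2,
                    coastal_position_km = c(10, 0))
  expect_error(coastal_distance_matrix(bad), class = "kelp_ordering_error")
})

test_that("distance matrices round-trip through TSV", {
  dir <- withr::local_tempdir()
  lt <- data.frame(locality = c("A", "B", "C"), order_index = 1:3,
                   coastal_position_km = c(0, 12.5, 40))
  m <- coastal_distance_matrix(lt)
  p <- file.path(dir, "m.tsv")
  write_distance_matrix(m, p)
  m2 <- read_distance_matrix(p, kind = "coastal_km")
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
})
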