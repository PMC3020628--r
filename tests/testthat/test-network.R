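test_that("parsimony probability and connection limit behave monotonically", {
  expect_error(connection_limit(629, 1.2), class = "kelp_parameter_error")
  expect_error(connection_limit(629, 0), class = "kelp_parameter_error")
  expect_error(connection_limit(0, 0.9), class = "kelp_parameter_error")

  # probability decreases as differences accumulate
  p <- parsimony_probability(1:40, 629)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(parsimony_probability(0, 629), 1)

  # limit non-increasing in confidence, non-decreasing in length
  for (L in c(200, 629, 886)) {
    expect_gte(connection_limit(L, 0.90), connection_limit(L, 0.95))
  }
  lims <- vapply(seq(100, 1000, 100), connection_limit, integer(1),
                 confidence = 0.95)
  expect_true(all(diff(lims) >= 0))
})

test_that("connection limit matches the independently coded probability recursion", {
  for (L in c(100, 400, 629, 1000)) {
    for (conf in c(0.90, 0.95)) {
      expect_equal(connection_limit(L, conf), oracle_connection_limit(L, conf))
    }
  }
})

test_that("build_network joins close pairs through hypothetical intermediates and severs distant ones", {
  a <- "AAAAAAAAAA"
  # distance 1: a single edge
  ht1 <- make_ht(c(a, "AAAAAAAAAT"), c("L1", "L2"))
  net1 <- build_network(ht1, limit = 10)
  expect_equal(nrow(net1$edges), 1)
  expect_equal(length(net1$components), 1)
  expect_equal(sum(!net1$nodes$observed), 0)

  # distance 3 within the limit: 2 hypothetical intermediates, path 3
  b3 <- "AAAAAAATTT"
  ht3 <- make_ht(c(a, b3), c("L1", "L2"))
  net3 <- build_network(ht3, limit = 10)
  expect_equal(sum(!net3$nodes$observed), 2)
  expect_equal(length(net3$components), 1)
  gd <- igraph::distances(net3$graph)
  h_a <- net3$nodes$id[net3$nodes$observed][1]
  h_b <- net3$nodes$id[net3$nodes$observed][2]
  expect_equal(unname(gd[h_a, h_b]), 3)
  # hypothetical intermediates sit on the path: degree 2
  deg <- igraph::degree(net3$graph)
  expect_true(all(deg[net3$nodes$id[!net3$nodes$observed]] == 2))

  # distance 3 beyond limit 2: two components, no edges
  net_cut <- build_network(ht3, limit = 2)
  expect_equal(nrow(net_cut$edges), 0)
  expect_equal(length(net_cut$components), 2)

  # star: k haplotypes one step from a hub form one component
  hub <- "CCCCCCCCCC"
  tips <- c("ACCCCCCCCC", "CTCCCCCCCC", "CCGCCCCCCC", "CCCACCCCCC")
  ht_star <- make_ht(c(rep(hub, 4), tips),
                     rep(c("L1", "L2"), each = 4))
  net_star <- build_network(ht_star, limit = 5)
  expect_equal(length(net_star$components), 1)
  expect_equal(length(net_star$components[[1]]), 5)
})

test_that("subnetworks are ordered by total frequency and match the closure oracle", {
  withr::local_seed(14)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    seqs <- character(0)
    while (length(unique(seqs)) < k) seqs <- replicate(k, rand_seq(20))
    copies <- sample(1:3, k, replace = TRUE)
    ht <- make_ht(rep(seqs, times = copies), rep("L1", sum(copies)))
    limit <- sample(1:8, 1)
    net <- tryCatch(build_network(ht, limit), error = function(e) NULL)
    expect_false(is.null(net))
    got <- canonical_partition(
      lapply(subnetworks(net),
             function(cc) unname(ht$haplotype_seqs[cc])))
    want <- oracle_components(unname(ht$haplotype_seqs),
                              unname(ht$haplotype_seqs), limit)
    expect_equal(got, want)
  }
})

test_that("component structure is invariant to haplotype input order", {
  withr::local_seed(31)
  base <- rand_seq(25)
  pool <- c(base, mutate_sequence(base, 1), mutate_sequence(base, 2),
            mutate_sequence(base, 9), mutate_sequence(base, 12))
  seqs <- sample(pool, 20, replace = TRUE)
  locs <- sample(c("L1", "L2"), 20, replace = TRUE)
  net_a <- build_network(make_ht(seqs, locs), limit = 5)
  perm <- sample(20)
  net_b <- build_network(make_ht(seqs[perm], locs[perm]), limit = 5)
  part <- function(net, ht) canonical_partition(
    lapply(net$components, function(cc) unname(ht$haplotype_seqs[cc])))
  expect_equal(part(net_a, make_ht(seqs, locs)),
               part(net_b, make_ht(seqs[perm], locs[perm])))
})

test_that("graph distance equals raw differences on additive (tree-like) instances", {
  # chain built on disjoint mutated sites: distances are additive
  h1 <- paste(rep("A", 30), collapse = "")
  h2 <- sub("^A", "G", h1)                       # 1 step
  h3 <- sub("AA$", "GG", h2)                     # +2 steps
  h4 <- sub("^(.{10})A", "\\1C", h3)             # +1 step
  # limit 2 admits only the chain steps themselves, so no implied
  # equal-length alternatives are even considered
  ht <- make_ht(c(h1, h2, h3, h4), c("L1", "L1", "L2", "L2"))
  net <- build_network(ht, limit = 2)
  expect_equal(nrow(net$ambiguous_links), 0)
  expect_equal(length(net$components), 1)
  gd <- igraph::distances(net$graph)
  for (i in 1:3) for (j in (i + 1):4) {
    ida <- names(ht$haplotype_seqs)[match(c(h1, h2, h3, h4)[i],
                                          ht$haplotype_seqs)]
    idb <- names(ht$haplotype_seqs)[match(c(h1, h2, h3, h4)[j],
                                          ht$haplotype_seqs)]
    expect_equal(unname(gd[ida, idb]),
                 raw_differences(c(h1, h2, h3, h4)[i], c(h1, h2, h3, h4)[j]))
  }
})

test_that("equal-length alternative connections are recorded as ambiguous links", {
  # hub plus two one-step tips: the tip-tip pair (2 steps) duplicates
  # the existing 2-step path through the hub -> classic equal-length loop
  h1 <- "AAAAAAAAAA"
  h2 <- "GAAAAAAAAA"
  h3 <- "AGAAAAAAAA"
  ht <- make_ht(c(h1, h2, h3), c("L1", "L2", "L3"))
  net <- build_network(ht, limit = 5)
  expect_equal(length(net$components), 1)
  expect_equal(nrow(net$ambiguous_links), 1)
  expect_equal(net$ambiguous_links$steps, 2)
})

test_that("network export writes graphml, tables and components", {
  dir <- withr::local_tempdir()
  ht <- make_ht(c("AAAA", "AAAT", "AAGT"), c("L1", "L1", "L2"))
  net <- build_network(ht, limit = 3)
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  nodes <- read.delim(paths[["nodes"]])
  expect_equal(sum(nodes$observed), 3)
  comp <- jsonlite::read_json(paths[["components"]])
  expect_equal(length(comp), length(net$components))
})
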