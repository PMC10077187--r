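test_that("connectance and links per species follow their definitions", {
  m <- incidence_with_links(4, 5, 10)
  expect_equal(connectance(m), 10 / 20)
  expect_equal(links_per_species(m), 10 / 9)
  expect_equal(connectance(matrix(1, 3, 3)), 1)
  # a single edge leaves one node per guild after pruning isolates
  one <- bipartite_network(named_matrix(matrix(c(1, 0, 0, 0), 2)))
  expect_equal(links_per_species(one), 0.5)
  expect_error(connectance(matrix(0, 2, 2)), "empty")
})

test_that("NODF matches hand-enumerated values and the brute-force oracle", {
  expect_equal(nodf(staircase3()), 100)
  expect_equal(nodf(diag(2)), 0)
  # [[1,1,0],[1,0,1]]: row pair equal fill (0); col pairs 100, 100, 0
  m <- matrix(c(1, 1, 0, 1, 0, 1), 2, byrow = TRUE)
  expect_equal(nodf(m), 50)
  set.seed(99)
  for (k in 1:50) {
    r <- matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6)
    if (sum(r) == 0) next
    expect_equal(nodf(r), nodf_oracle(r), tolerance = 1e-9)
  }
  expect_error(nodf(matrix(0, 3, 3)), "all-zero")
  expect_error(nodf(matrix(1, 1, 3)), "at least 2")
})

test_that("duplicate-fill rows contribute nothing to NODF (decreasing fill)", {
  m <- staircase3()
  m2 <- rbind(m, m[3, ])           # duplicate of the sparsest row
  # the new equal-fill pair contributes 0, so NODF drops below 100
  expect_lt(nodf(m2), 100)
  expect_equal(nodf_oracle(m2), nodf(m2), tolerance = 1e-9)
})

test_that("d' spans its endpoints and matches the direct formula", {
  # uniform complete matrix: every node's shares equal the marginals -> 0
  u <- named_matrix(matrix(1, 3, 3))
  expect_equal(unname(specialization_d(u, "rows")), rep(0, 3))
  # exclusive partners -> 1
  expect_equal(unname(specialization_d(named_matrix(diag(2)), "rows")),
               c(1, 1))
  # random 4x4 integer matrix vs direct evaluation of the formula
  set.seed(12)
  a <- matrix(rpois(16, 3), 4)
  a[1, ] <- c(5, 0, 0, 0)
  a <- named_matrix(a)
  dp <- specialization_d(a, "rows")
  m <- sum(a); q <- colSums(a) / m
  oracle <- vapply(1:4, function(i) {
    Ai <- sum(a[i, ])
    ps <- a[i, a[i, ] > 0] / Ai
    d <- sum(ps * log(ps / q[a[i, ] > 0]))
    min(max(d / log(m / Ai), 0), 1)
  }, numeric(1))
  expect_equal(unname(dp), oracle, tolerance = 1e-9)
})

test_that("perfect specialists are exclusive pairing partners", {
  expect_equal(count_perfect_specialists(named_matrix(diag(2))), 4)
  expect_equal(count_perfect_specialists(named_matrix(matrix(1, 3, 3))), 0)
  # mixed network with one exclusive pair -> exactly its two endpoints
  m <- named_matrix(rbind(c(0, 2, 1), c(0, 1, 2), c(3, 0, 0)))
  expect_equal(count_perfect_specialists(m), 2)
  dp <- specialization_d(m, "rows")
  expect_equal(unname(dp["r3"]), 1)
})

test_that("interaction diversity and evenness behave as entropies", {
  m <- named_matrix(rbind(c(1, 1), c(1, 1)))
  expect_equal(interaction_shannon(m), log(4))
  expect_equal(interaction_evenness(m), 1)
  single <- named_matrix(rbind(c(5, 0), c(0, 0)))
  expect_equal(interaction_shannon(single), 0)
  expect_equal(interaction_evenness(matrix(c(5, 0, 0, 0), 2)), 0)
  # scale invariance
  set.seed(2)
  w <- matrix(runif(12), 3)
  expect_equal(interaction_shannon(w), interaction_shannon(10 * w))
  expect_gte(interaction_evenness(w), 0)
  expect_lte(interaction_evenness(w), 1)
})

test_that("linkage density equals the effective-partner average", {
  expect_equal(linkage_density(matrix(1, 2, 2)), 2)     # K22 unit weights
  expect_equal(linkage_density(matrix(c(1, 0, 0, 0), 2)), 1)  # single link
  set.seed(3)
  w <- matrix(rexp(20), 4)
  expect_lte(linkage_density(w), max(dim(w)))
})

test_that("guild clustering matches explicit triangle enumeration", {
  expect_equal(guild_cluster_coefficient(matrix(1, 3, 4), "rows"), 1)
  expect_equal(guild_cluster_coefficient(diag(3), "rows"), 0)
  # rows r1..r3 share a hub column; r4 linked to r1 via a private column
  b <- rbind(c(1, 1, 0, 0, 0),
             c(1, 0, 1, 0, 0),
             c(1, 0, 0, 1, 0),
             c(0, 1, 0, 0, 1))
  # projection: triangle r1r2r3 plus pendant edge r1-r4
  # local cc: r1 = 1/3, r2 = r3 = 1, r4 = 0
  expect_equal(guild_cluster_coefficient(b, "rows"),
               mean(c(1 / 3, 1, 1, 0)))
})

test_that("compartments count connected components", {
  expect_equal(compartments(generate_modular_incidence(3, 2, 2)), 3)
  expect_equal(compartments(matrix(1, 3, 3)), 1)
  expect_equal(compartments(diag(5)), 5)
})

test_that("the network report is complete and internally consistent", {
  set.seed(6)
  w <- matrix(rbinom(48, 1, 0.4) * runif(48, 0.6, 1), 6)
  net <- suppressWarnings(bipartite_network(named_matrix(w)))
  rep <- network_report(net)
  expect_true(all(!vapply(rep, is.null, logical(1))))
  expect_equal(rep$links_per_species * (rep$n_microeukaryotes +
                                          rep$n_bacteria), rep$n_links)
  expect_equal(rep$connectance,
               rep$n_links / (rep$n_microeukaryotes * rep$n_bacteria))
  k22 <- network_report(matrix(1, 2, 2))
  expect_equal(k22$connectance, 1)
  expect_equal(k22$links_per_species, 1)
  expect_equal(k22$n_compartments, 1)
  nm <- node_metrics(net)
  expect_identical(nrow(nm), rep$n_microeukaryotes + rep$n_bacteria)
  expect_true(all(nm$degree >= 1))
  expect_true(all(nm$dprime >= 0 & nm$dprime <= 1))
})
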