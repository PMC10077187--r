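test_that("the generator is deterministic under a seed", {
  spec <- synthetic_spec(n_samples = 10, n_bacteria = 8, n_eukaryotes = 5,
                         depth_bacteria = 500, depth_eukaryotes = 300,
                         planted = planted_edges(1, 1), seed = 3)
  a <- generate_community(spec)
  b <- generate_community(spec)
  expect_identical(a$bacteria$counts, b$bacteria$counts)
  expect_identical(a$eukaryotes$counts, b$eukaryotes$counts)
  expect_identical(colSums(a$bacteria$counts),
                   setNames(rep(500, 10), colnames(a$bacteria$counts)))
})

test_that("planted latent correlations appear in the basis draws", {
  # null case: no planted edges, cross-kingdom latent correlations centre on 0
  spec0 <- synthetic_spec(n_samples = 100, n_bacteria = 15, n_eukaryotes = 10,
                          depth_bacteria = 1000, depth_eukaryotes = 1000,
                          planted = planted_edges(0, 0), seed = 5)
  z <- generate_community(spec0)$truth$basis
  cc <- cor(t(z[1:10, ]), t(z[11:25, ]))
  expect_lt(abs(mean(cc)), 0.05)

  # one planted pair at 0.9, n = 200: latent sample correlation above 0.6
  spec1 <- synthetic_spec(n_samples = 200, n_bacteria = 12, n_eukaryotes = 8,
                          depth_bacteria = 20000, depth_eukaryotes = 20000,
                          planted = data.frame(euk = 1, bact = 1, sign = "+",
                                               magnitude = 0.9), seed = 11)
  sim <- generate_community(spec1)
  lat <- cor(sim$truth$basis["euk_0001", ], sim$truth$basis["bact_0001", ])
  expect_gt(lat, 0.6)
  # negative sign flips the latent correlation
  spec2 <- synthetic_spec(n_samples = 200, n_bacteria = 12, n_eukaryotes = 8,
                          depth_bacteria = 2000, depth_eukaryotes = 2000,
                          planted = data.frame(euk = 2, bact = 3, sign = "-",
                                               magnitude = 0.9), seed = 12)
  sim2 <- generate_community(spec2)
  expect_lt(cor(sim2$truth$basis["euk_0002", ],
                sim2$truth$basis["bact_0003", ]), -0.6)
})

test_that("invalid planted specifications are rejected", {
  expect_error(synthetic_spec(planted = data.frame(euk = 1, bact = 1,
                                                   sign = "+",
                                                   magnitude = 1.2)),
               "magnitudes")
  expect_error(synthetic_spec(planted = data.frame(euk = c(1, 1),
                                                   bact = c(1, 1),
                                                   sign = "+",
                                                   magnitude = 0.5)),
               "duplicate")
  expect_error(synthetic_spec(n_eukaryotes = 2,
                              planted = data.frame(euk = 5, bact = 1,
                                                   sign = "+",
                                                   magnitude = 0.5)),
               "nonexistent")
  # an inconsistent correlation pattern cannot be embedded
  pl <- data.frame(euk = c(1, 2, 1, 2), bact = c(1, 1, 2, 2),
                   sign = c("+", "+", "+", "-"), magnitude = 0.95)
  expect_error(generate_community(
    synthetic_spec(n_samples = 10, n_bacteria = 3, n_eukaryotes = 3,
                   depth_bacteria = 100, depth_eukaryotes = 100,
                   planted = pl, seed = 1)),
    "positive definite")
})

test_that("nested incidence fixtures are perfectly nested by construction", {
  expect_equal(unname(generate_nested_incidence(3, 3)),
               unname(staircase3()))
  expect_equal(nodf(generate_nested_incidence(5, 5)), 100)
  expect_error(generate_nested_incidence(1, 3), "at least 2 rows")
  expect_error(generate_nested_incidence(4, 4, fill = 0.1), "infeasible")
  m <- generate_nested_incidence(4, 6, fill = 0.6)
  expect_equal(sum(m), round(0.6 * 24))
  expect_true(all(diff(rowSums(m)) < 0))
})

test_that("modular incidence fixtures are block-diagonal with known labels", {
  m <- generate_modular_incidence(2, 2, 2)
  expect_identical(dim(m), c(4L, 4L))
  expect_identical(sum(m), 8L)
  expect_identical(m[1:2, 3:4], matrix(0L, 2, 2,
                                       dimnames = dimnames(m[1:2, 3:4])))
  expect_equal(compartments(m), 2)
  part <- list(rows = attr(m, "row_block"), cols = attr(m, "col_block"))
  expect_equal(barber_q(m, part), 0.5)
  expect_error(generate_modular_incidence(1), "at least 2 blocks")
})
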