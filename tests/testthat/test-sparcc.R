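test_that("log-ratio variation matrix matches the naive per-pair loop", {
  set.seed(4)
  f <- matrix(runif(30, 0.1, 1), 3); f <- sweep(f, 2, colSums(f), "/")
  rownames(f) <- paste0("o", 1:3)
  t_mat <- log_ratio_variances(f)
  # oracle: explicit double loop
  for (i in 1:3) for (j in 1:3) {
    expect_equal(t_mat[i, j], if (i == j) 0 else var(log(f[i, ] / f[j, ])),
                 tolerance = 1e-12)
  }
  # identical rows and scaled rows have zero log-ratio variance
  g <- rbind(f[1, ], f[1, ], 0.3 * f[1, ], f[2, ])
  tg <- log_ratio_variances(g)
  expect_equal(tg[1, 2], 0, tolerance = 1e-12)
  expect_equal(tg[1, 3], 0, tolerance = 1e-12)
  expect_error(log_ratio_variances(f[, 1:2]), "3 samples")
})

test_that("basis variances solve the SparCC linear system", {
  # all pairwise t = 2 -> all omega^2 = 1 by symmetry
  tt <- matrix(2, 5, 5); diag(tt) <- 0
  expect_equal(unname(estimate_basis_variances(tt)^2), rep(1, 5))
  # 3-OTU closed form: omega_1^2 = (t12 + t13 - t23) / 2
  set.seed(7)
  f <- matrix(runif(30, 0.05, 1), 3); f <- sweep(f, 2, colSums(f), "/")
  t3 <- log_ratio_variances(f)
  w <- estimate_basis_variances(t3)
  expect_equal(w[1]^2, (t3[1, 2] + t3[1, 3] - t3[2, 3]) / 2,
               tolerance = 1e-12)
  expect_equal(w[2]^2, (t3[1, 2] + t3[2, 3] - t3[1, 3]) / 2,
               tolerance = 1e-12)
  # all-zero t floors at the epsilon
  z <- matrix(0, 4, 4)
  expect_true(all(estimate_basis_variances(z) > 0))
  expect_error(estimate_basis_variances(matrix(0, 2, 2)), "3 OTUs")
})

test_that("correlation estimates are symmetric, bounded, exclusion-capped", {
  # equal variation everywhere -> zero correlations
  set.seed(8)
  n <- 40
  base <- exp(rnorm(n))
  f <- rbind(o1 = base * exp(rnorm(n, sd = 1)),
             o2 = base * exp(rnorm(n, sd = 1)),
             o3 = base * exp(rnorm(n, sd = 1)),
             o4 = base * exp(rnorm(n, sd = 1)))
  f <- sweep(f, 2, colSums(f), "/")
  fit <- estimate_correlations(f)
  expect_identical(fit$rho, t(fit$rho))
  expect_identical(unname(diag(fit$rho)), rep(1, 4))
  expect_true(all(abs(fit$rho) <= 1))
  expect_lte(nrow(fit$excluded_pairs), 10)
  # exactly equal t gives exactly zero off-diagonals
  tt <- matrix(3, 4, 4); diag(tt) <- 0
  w <- estimate_basis_variances(tt)
  rho <- (outer(w^2, w^2, "+") - tt) / (2 * outer(w, w))
  expect_equal(unname(rho[upper.tri(rho)]), rep(0, 6), tolerance = 1e-12)
})

test_that("SparCC recovers a strong planted association", {
  spec <- synthetic_spec(n_samples = 200, n_bacteria = 12, n_eukaryotes = 8,
                         depth_bacteria = 20000, depth_eukaryotes = 20000,
                         planted = data.frame(euk = 1, bact = 1, sign = "+",
                                              magnitude = 0.9), seed = 11)
  sim <- generate_community(spec)
  pooled <- rbind(sim$eukaryotes$counts, sim$bacteria$counts)
  fit <- sparcc(pooled, n_draws = 20, seed = 3)
  lat <- cor(sim$truth$basis["euk_0001", ], sim$truth$basis["bact_0001", ])
  est <- fit$rho["euk_0001", "bact_0001"]
  expect_lt(abs(est - 0.9), 0.15)
  expect_lt(abs(est - lat), 0.15)
  # determinism and the n_draws = 1 identity
  expect_identical(sparcc(pooled, n_draws = 5, seed = 3)$rho,
                   sparcc(pooled, n_draws = 5, seed = 3)$rho)
  one <- sparcc(pooled, n_draws = 1, seed = 3)
  expect_s3_class(one, "sparcc_fit")
  # median aggregation stays inside the per-draw envelope
  fits <- with(list(), {
    set.seed(3)
    lapply(1:5, function(i)
      estimate_correlations(biparcc:::.draw_fractions(pooled)))
  })
  arr <- simplify2array(lapply(fits, `[[`, "rho"))
  med <- apply(arr, c(1, 2), median)
  expect_true(all(med >= apply(arr, c(1, 2), min) - 1e-12))
  expect_true(all(med <= apply(arr, c(1, 2), max) + 1e-12))
})

test_that("permutation p-values separate real from null associations", {
  set.seed(21)
  n <- 40
  lat <- rnorm(n)
  counts <- rbind(
    a = rpois(n, exp(2 + 1.5 * lat)),          # a and b strongly coupled
    b = rpois(n, exp(2 + 1.5 * lat)),
    c = rpois(n, exp(rnorm(n) + 2)),
    d = rpois(n, exp(rnorm(n) + 2)),
    e = rpois(n, exp(rnorm(n) + 2)))
  colnames(counts) <- paste0("s", 1:n)
  fit <- sparcc(counts, n_draws = 10, seed = 1)
  sig <- sparcc_pvalues(counts, fit, n_boot = 60, seed = 2)
  expect_true(all(sig$p[upper.tri(sig$p)] >= 0 &
                    sig$p[upper.tri(sig$p)] <= 1))
  expect_true(all(is.na(diag(sig$p))))
  expect_lt(sig$p["a", "b"], 0.05)
  # reproducible under seed
  sig2 <- sparcc_pvalues(counts, fit, n_boot = 60, seed = 2)
  expect_identical(sig$p, sig2$p)
  expect_error(sparcc_pvalues(counts, fit, n_boot = 5), ">= 20")
})

test_that("edge selection applies strict rho and p thresholds", {
  rho <- matrix(c(1, 0.61, 0.60, 0.9,
                  0.61, 1, -0.7, 0.1,
                  0.60, -0.7, 1, 0.2,
                  0.9, 0.1, 0.2, 1), 4,
                dimnames = list(letters[1:4], letters[1:4]))
  p <- matrix(0.01, 4, 4, dimnames = dimnames(rho))
  p["a", "d"] <- p["d", "a"] <- 0.06
  diag(p) <- NA
  e <- significant_edges(rho, p, 0.6, 0.05)
  key <- paste(e$source, e$target)
  expect_true("a b" %in% key)        # rho 0.61, p 0.01 -> kept
  expect_false("a c" %in% key)       # rho 0.60 exactly -> dropped
  expect_false("a d" %in% key)       # rho 0.9 but p 0.06 -> dropped
  expect_true("b c" %in% key)        # negative edge kept with sign
  expect_identical(e$sign[key == "b c"], "negative")
})
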