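test_that("tanimoto matches an index-set oracle and its boundary conventions", {
  a <- c(1, 1, 1, 0, 0)
  b <- c(0, 1, 1, 1, 0)
  expect_equal(tanimoto(a, b), 0.5)  # 2 shared over 4 union
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(rep(0, 5), rep(0, 5)), 0)  # 0/0 convention
  expect_error(tanimoto(a, c(1, 0)), "length")

  set.seed(9)
  for (i in 1:200) {
    x <- rbinom(64, 1, 0.3)
    y <- rbinom(64, 1, 0.3)
    ix <- which(x == 1); iy <- which(y == 1)
    u <- length(union(ix, iy))
    oracle <- if (u == 0) 0 else length(intersect(ix, iy)) / u
    expect_identical(tanimoto(x, y), oracle)
    expect_identical(tanimoto(x, y), tanimoto(y, x))
  }
})

test_that("pair_tanimoto agrees with the scalar version and flags missing drugs", {
  b <- small_bundle()
  pairs <- enumerate_pairs(b$fingerprints$drug_ids[1:12])
  sims <- pair_tanimoto(pairs, b$fingerprints)
  expect_true(all(sims >= 0 & sims <= 1))
  for (i in seq(1, nrow(pairs), by = 9)) {
    expect_equal(sims[i], tanimoto(b$fingerprints$bits[pairs$drug_a[i], ],
                                   b$fingerprints$bits[pairs$drug_b[i], ]))
  }
  expect_error(pair_tanimoto(data.frame(drug_a = "nope", drug_b = pairs$drug_b[1]),
                             b$fingerprints), "nope")
})

test_that("similarity density is a floored, normalized distribution", {
  # degenerate: all mass in the bin containing 0.3
  d <- estimate_similarity_density(rep(0.3, 500), method = "histogram",
                                   parameter = 20)
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  expect_equal(which.max(d$density), findInterval(0.3, d$breaks))
  expect_true(all(d$density > 0))

  # near-uniform input gives a near-flat histogram
  set.seed(10)
  u <- estimate_similarity_density(runif(10000), parameter = 20)
  expect_lt(max(u$density) / min(u$density), 1.5)

  # bimodal input: interior bins sit at the floor
  two <- estimate_similarity_density(c(rep(0.1, 500), rep(0.9, 500)),
                                     parameter = 10)
  interior <- two$density[4:7]
  expect_true(all(interior == min(two$density)))
  expect_gt(density_at(two, 0.1) / density_at(two, 0.5), 100)

  expect_error(estimate_similarity_density(c(0.5, 1.2)), "0, 1")
  expect_error(estimate_similarity_density(numeric(0)), "no similarities")
})

test_that("kde density estimation stays normalized and positive", {
  set.seed(11)
  d <- estimate_similarity_density(rbeta(2000, 2, 5), method = "kde")
  expect_equal(sum(d$density), 1, tolerance = 1e-12)
  expect_true(all(density_at(d, seq(0, 1, 0.05)) > 0))
  # constant input must not break the bandwidth rule
  expect_silent(estimate_similarity_density(rep(0.4, 50), method = "kde"))
})

test_that("negative sets honour size, uniqueness and reproducibility", {
  set.seed(12)
  n <- 2000
  pairs <- data.frame(drug_a = sprintf("A%04d", 1:n),
                      drug_b = sprintf("B%04d", 1:n))
  sims <- runif(n)
  sets <- sample_negative_sets(pairs, sims, set_size = 300, n_sets = 5, seed = 21)
  expect_length(sets, 5)
  for (s in sets) {
    expect_equal(nrow(s$pairs), 300)
    expect_equal(anyDuplicated(s$indices), 0)
    expect_equal(s$seed, 21)
  }
  again <- sample_negative_sets(pairs, sims, set_size = 300, n_sets = 5, seed = 21)
  expect_identical(lapply(sets, `[[`, "indices"), lapply(again, `[[`, "indices"))
  expect_error(sample_negative_sets(pairs, sims, set_size = n + 1, seed = 1),
               "exceeds")
})

test_that("set_size equal to the pool returns every negative regardless of weights", {
  pairs <- data.frame(drug_a = sprintf("A%02d", 1:100),
                      drug_b = sprintf("B%02d", 1:100))
  sims <- c(rep(0.1, 90), rep(0.9, 10))
  sets <- sample_negative_sets(pairs, sims, set_size = 100, n_sets = 2, seed = 4)
  for (s in sets) expect_setequal(s$indices, 1:100)
})

test_that("flat density yields uniform inclusion; sparse similarities are over-drawn", {
  # equal similarities give equal weights: chi-square cannot reject uniform
  set.seed(13)
  n <- 400
  pairs <- data.frame(drug_a = sprintf("A%03d", 1:n), drug_b = sprintf("B%03d", 1:n))
  sims_flat <- rep(0.5, n)
  sets <- sample_negative_sets(pairs, sims_flat, set_size = 100, n_sets = 200,
                               seed = 31, parameter = 10)
  incl <- tabulate(unlist(lapply(sets, `[[`, "indices")), nbins = n)
  expect_gt(stats::chisq.test(incl)$p.value, 0.01)

  # planted bimodal pool: the rare high-similarity 10% is over-included and
  # inclusion frequency decreases with the density at a pair's similarity
  sims_bi <- c(runif(3600, 0.15, 0.25), runif(400, 0.75, 0.85))
  sets_bi <- sample_negative_sets(pairs <- data.frame(
    drug_a = sprintf("A%04d", 1:4000), drug_b = sprintf("B%04d", 1:4000)),
    sims_bi, set_size = 400, n_sets = 200, seed = 32)
  incl_bi <- tabulate(unlist(lapply(sets_bi, `[[`, "indices")), nbins = 4000)
  rare_rate <- mean(incl_bi[3601:4000]) / 200
  common_rate <- mean(incl_bi[1:3600]) / 200
  expect_gt(rare_rate, 2 * common_rate)
  dens <- density_at(estimate_similarity_density(sims_bi), sims_bi)
  sp <- stats::cor.test(dens, incl_bi, method = "spearman", exact = FALSE,
                        alternative = "less")
  expect_lt(sp$p.value, 0.01)
})
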