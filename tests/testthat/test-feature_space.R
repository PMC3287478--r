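make_dm <- function(values) descriptor_matrix(as.matrix(values))

test_that("cleaning drops near-constant and error columns by the stated rules", {
  set.seed(1)
  n <- 100
  vals <- cbind(
    informative = rnorm(n),
    const95 = c(rep(1, 95), rnorm(5)),        # modal value in 95% of drugs
    const90 = c(rep(2, 90), rnorm(10)),       # exactly 90%: boundary, kept
    with_na = c(NA, rnorm(n - 1)))
  rownames(vals) <- sprintf("D%03d", 1:n)
  D <- make_dm(vals)
  cleaned <- clean_descriptors(D, near_constant_frac = 0.9)
  expect_setequal(cleaned$descriptor_names, c("informative", "const90"))
  dropped <- attr(cleaned, "dropped")
  expect_equal(dropped$reason[dropped$name == "with_na"], "error")
  expect_equal(dropped$reason[dropped$name == "const95"], "near_constant")
})

test_that("cleaning is idempotent and errors when nothing survives", {
  set.seed(2)
  vals <- matrix(rnorm(200), 50, 4,
                 dimnames = list(sprintf("D%02d", 1:50), paste0("x", 1:4)))
  once <- clean_descriptors(make_dm(vals))
  twice <- clean_descriptors(once)
  expect_identical(once$values, twice$values)
  all_const <- make_dm(matrix(1, 10, 2, dimnames = list(paste0("D", 1:10), c("a", "b"))))
  expect_error(clean_descriptors(all_const), "all descriptors dropped")
})

test_that("component count is minimal for the variance target", {
  # closed-form 2D oracle: eigenvalues of the covariance give the split
  set.seed(3)
  n <- 400
  x1 <- rnorm(n, sd = 2)
  x2 <- rnorm(n, sd = 1)
  D <- make_dm(matrix(c(x1, x2), ncol = 2,
                      dimnames = list(sprintf("D%03d", 1:n), c("a", "b"))))
  ev <- eigen(stats::cov(cbind(x1, x2)))$values
  frac1 <- ev[1] / sum(ev)   # ~0.8: below 0.9, so k must be 2
  expect_lt(frac1, 0.9)
  space <- fit_pc_space(D, variance_target = 0.9, standardize = FALSE)
  expect_equal(space$k, 2)
  expect_equal(sum(space$explained_fraction), 1, tolerance = 1e-10)
  # explained fractions agree with the covariance eigenvalues
  expect_equal(space$explained_fraction, ev / sum(ev), tolerance = 1e-8)

  # target 1.0 on full-rank data keeps every component
  set.seed(4)
  full <- make_dm(matrix(rnorm(60 * 5), 60, 5,
                         dimnames = list(sprintf("D%02d", 1:60), paste0("x", 1:5))))
  expect_equal(fit_pc_space(full, variance_target = 1.0)$k, 5)
})

test_that("minimality and orthonormality hold across random matrices", {
  for (s in 1:5) {
    set.seed(s)
    D <- make_dm(matrix(rnorm(50 * 20), 50, 20,
                        dimnames = list(sprintf("D%02d", 1:50), paste0("x", 1:20))))
    sp <- fit_pc_space(D, variance_target = 0.9)
    cum <- cumsum(sp$explained_fraction)
    expect_gte(cum[sp$k], 0.9)
    if (sp$k > 1) expect_lt(cum[sp$k - 1], 0.9)
    expect_true(all(diff(sp$explained_fraction) <= 1e-12))
    gram <- crossprod(sp$loadings)
    expect_lt(max(abs(gram - diag(sp$k))), 1e-8)
  }
})

test_that("projection matches direct matrix arithmetic and centering", {
  set.seed(5)
  D <- make_dm(matrix(rnorm(30 * 6), 30, 6,
                      dimnames = list(sprintf("D%02d", 1:30), paste0("x", 1:6))))
  sp <- fit_pc_space(D, variance_target = 0.9)
  scores <- project(D, sp)
  # single new drug vs. brute-force (x - center)/scale %*% loadings
  x <- rnorm(6)
  newD <- descriptor_matrix(matrix(x, 1, 6, dimnames = list("NEW", paste0("x", 1:6))))
  expect_equal(as.numeric(project(newD, sp)),
               as.numeric(((x - sp$center) / sp$scale) %*% sp$loadings),
               tolerance = 1e-12)
  # a drug sitting at the column means projects to the origin
  meanD <- descriptor_matrix(matrix(sp$center, 1, 6,
                                    dimnames = list("MEAN", paste0("x", 1:6))))
  expect_equal(max(abs(project(meanD, sp))), 0, tolerance = 1e-12)
  # projecting the training matrix reproduces the fit scores (vs prcomp as
  # an independent reference, up to the sign convention)
  pr <- prcomp(D$values, center = TRUE, scale. = TRUE)
  expect_equal(abs(unname(scores)), abs(unname(pr$x[, 1:sp$k])), tolerance = 1e-8)
})

test_that("full-rank projection reconstructs the standardized data", {
  set.seed(6)
  D <- make_dm(matrix(rnorm(40 * 8), 40, 8,
                      dimnames = list(sprintf("D%02d", 1:40), paste0("x", 1:8))))
  sp <- fit_pc_space(D, variance_target = 1.0)
  scores <- project(D, sp)
  back <- scores %*% t(sp$loadings)
  std <- scale(D$values, center = sp$center, scale = sp$scale)
  expect_lt(max(abs(back - std)), 1e-6)
})

test_that("fit and projection reject bad input", {
  set.seed(7)
  D <- make_dm(matrix(rnorm(20 * 3), 20, 3,
                      dimnames = list(sprintf("D%02d", 1:20), c("a", "b", "c"))))
  expect_error(fit_pc_space(D, variance_target = 0), "variance_target")
  expect_error(fit_pc_space(D, variance_target = 1.5), "variance_target")
  sp <- fit_pc_space(D)
  D2 <- make_dm(matrix(rnorm(20 * 2), 20, 2,
                       dimnames = list(sprintf("D%02d", 1:20), c("a", "b"))))
  expect_error(project(D2, sp), "c")
  withNA <- D
  withNA$values[1, 1] <- NA
  withNA$missing_mask[1, 1] <- TRUE
  expect_error(fit_pc_space(withNA), "clean_descriptors")
})
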