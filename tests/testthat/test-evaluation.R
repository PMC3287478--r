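test_that("sensitivity/specificity counts match a brute-force confusion oracle", {
  # separable toy case
  cv <- sensitivity_specificity_curve(c(0.9, 0.1), c("positive", "negative"),
                                      thresholds = 0.5)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  # threshold below every score calls everything positive
  lo <- sensitivity_specificity_curve(c(0.9, 0.1), c("positive", "negative"),
                                      thresholds = 0)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)

  set.seed(30)
  scores <- runif(1000, -1, 1)
  labels <- sample(c("positive", "negative"), 1000, replace = TRUE)
  curve <- sensitivity_specificity_curve(scores, labels)
  for (i in seq(1, nrow(curve), by = 40)) {
    t <- curve$threshold[i]
    pred <- scores >= t
    expect_equal(curve$tp[i], sum(pred & labels == "positive"))
    expect_equal(curve$fp[i], sum(pred & labels == "negative"))
    expect_equal(curve$tn[i], sum(!pred & labels == "negative"))
    expect_equal(curve$fn[i], sum(!pred & labels == "positive"))
  }
  # confusion counts always sum to n; monotone in the threshold
  expect_true(all(curve$tp + curve$fp + curve$tn + curve$fn == 1000))
  expect_true(all(diff(curve$sensitivity) <= 0))
  expect_true(all(diff(curve$specificity) >= 0))
  expect_error(sensitivity_specificity_curve(scores, rep("positive", 1000)),
               "both classes")
})

test_that("sensitivity_at_specificity picks the best operating point", {
  curve <- sensitivity_specificity_curve(
    c(0.9, 0.8, 0.4, 0.3, 0.7, 0.2),
    c("positive", "positive", "positive", "negative", "negative", "negative"),
    thresholds = seq(0, 1, 0.1))
  expect_equal(sensitivity_at_specificity(curve, 1.0), 2 / 3)
  expect_true(is.na(sensitivity_at_specificity(curve, 1.1)))
})

test_that("fingerprint baselines reuse the Tanimoto machinery per kind", {
  b <- small_bundle()
  pairs <- enumerate_pairs(b$fingerprints$drug_ids[1:15])
  two <- fingerprint_baseline(pairs, list(x = b$fingerprints, y = b$fingerprints))
  expect_identical(two$x, two$y)  # identical matrices, identical curves
  expect_identical(two$x, pair_tanimoto(pairs, b$fingerprints))
  # single-bit fingerprints can only produce 0 or 1
  onebit <- fingerprint_set(matrix(c(1, 0, 1), ncol = 1,
                                   dimnames = list(c("A", "B", "C"), "b1")),
                            kind = "one-bit")
  sc <- fingerprint_baseline(enumerate_pairs(c("A", "B", "C")), onebit)[[1]]
  expect_true(all(sc %in% c(0, 1)))
})

test_that("domain matching ratio equals the base rate at the lowest threshold", {
  imap <- interaction_map(list(D1 = "T1", D2 = "T2", D3 = "T3", D4 = "T4"))
  dmap <- annotation_map(list(T1 = "PF00348", T2 = "PF00348", T3 = "PF99999"),
                         kind = "domain")
  pairs <- enumerate_pairs(c("D1", "D2", "D3", "D4"))
  scores <- c(0.9, 0.1, -0.5, 0.4, -0.2, 0.6)
  dm <- domain_match_ratio(pairs, scores, imap, dmap,
                           thresholds = c(-1, 0.85))
  # only the D1-D2 pair (shared PF00348) matches
  expect_equal(attr(dm, "base_rate"), 1 / 6)
  expect_equal(dm$ratio[dm$threshold == -1], attr(dm, "base_rate"))
  expect_equal(dm$ratio[dm$threshold == 0.85], 1)  # only D1-D2 is above
  none <- domain_match_ratio(pairs, scores, imap,
                             annotation_map(list(), kind = "domain"),
                             thresholds = c(-1, 2))
  expect_equal(none$ratio[1], 0)          # empty domain map: nothing matches
  expect_true(is.na(none$ratio[2]))       # no pair reaches the threshold
})

test_that("high-DRS negatives share domains far above the base rate on planted data", {
  b <- preset_bundle()
  scored <- preset_full_scored()
  neg <- scored[scored$label == "negative", ]
  dm <- domain_match_ratio(neg, neg$drs, b$interactions, b$domains,
                           thresholds = c(-1, 0, 0.5))
  base <- attr(dm, "base_rate")
  expect_gt(dm$ratio[dm$threshold == 0.5], base)
  expect_gt(dm$ratio[dm$threshold == 0], dm$ratio[dm$threshold == -1])
})

test_that("ATC matching follows prefix rules and level nesting", {
  expect_true(atc_match("N06AB05", "N06AX21", level = 2))
  expect_true(atc_match("N06AB05", "N06AX21", level = 3))
  expect_false(atc_match("N06AB05", "N02AB05", level = 2))
  expect_false(atc_match("N06AB05", "N06BX21", level = 3))
  # any matching code pair suffices
  expect_true(atc_match(c("A01AA01", "N06AB05"), "N06AX21", level = 2))
  expect_error(atc_match("N06AB05", "N06AX21", level = 7), "ATC level")

  amap <- annotation_map(list(Q = "N06AB05", P1 = "N06AX21", P2 = "N02AB05",
                              P3 = "N06AB01"), kind = "atc")
  ranking <- list(Q = c("P3", "P1", "P2"))
  c2 <- atc_match_curve("Q", ranking, amap, level = 2, max_rank = 3)
  c3 <- atc_match_curve("Q", ranking, amap, level = 3, max_rank = 3)
  expect_equal(c2$mean_matches, c(1, 2, 2))
  expect_equal(c3$mean_matches, c(1, 2, 2))  # N06AX21 shares the N06A prefix
  expect_true(all(c3$mean_matches <= c2$mean_matches))
  expect_true(all(diff(c2$mean_matches) >= 0))
})

test_that("per-group Pearson correlations handle exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  r <- score_correlation(x, 2 * x + 1)
  expect_equal(r$r, 1)
  r2 <- score_correlation(x, -x)
  expect_equal(r2$r, -1)
  set.seed(33)
  a <- rnorm(1000); bb <- rnorm(1000)
  expect_lt(abs(score_correlation(a, bb)$r), 0.1)
  expect_warning(rc <- score_correlation(x, rep(1, 5)), "undefined")
  expect_true(is.na(rc$r))
  g <- score_correlation(c(x, x), c(2 * x, -x), rep(c("g1", "g2"), each = 5))
  expect_equal(g$r, c(1, -1))
})
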