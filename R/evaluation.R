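# Evaluation statistics for the DRS and its fingerprint baselines:
# sensitivity/specificity threshold sweeps, protein-domain matching among
# high-scoring negative pairs, ATC-code matching along score rankings, and
# per-group Pearson correlations against external similarity scores.

#' Sensitivity/specificity over a threshold sweep
#'
#' At each threshold a pair is called positive when its score is >= the
#' threshold; sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param scores numeric scores.
#' @param labels `"positive"`/`"negative"` per score; both classes must be
#'   present.
#' @param thresholds sweep values (default 201 evenly spaced in \[-1, 1\]).
#' @return data.frame of class `eval_curve`: `threshold`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
sensitivity_specificity_curve <- function(scores, labels,
                                          thresholds = seq(-1, 1, length.out = 201)) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  npos <- sum(labels == "positive")
  nneg <- sum(labels == "negative")
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to compute sensitivity and specificity")
  pos_scores <- scores[labels == "positive"]
  neg_scores <- scores[labels == "negative"]
  tp <- vapply(thresholds, function(t) sum(pos_scores >= t), numeric(1))
  fp <- vapply(thresholds, function(t) sum(neg_scores >= t), numeric(1))
  out <- data.frame(threshold = thresholds,
                    sensitivity = tp / npos,
                    specificity = (nneg - fp) / nneg,
                    tp = tp, fp = fp, tn = nneg - fp, fn = npos - tp)
  class(out) <- c("eval_curve", "data.frame")
  out
}

#' Best sensitivity at a specificity floor
#'
#' Convenience for comparing methods at matched specificity: the maximum
#' sensitivity attained by any threshold whose specificity is at least
#' `specificity`.
#'
#' @param curve an [sensitivity_specificity_curve()] result.
#' @param specificity required specificity floor (default 0.8).
#' @export
sensitivity_at_specificity <- function(curve, specificity = 0.8) {
  ok <- curve$specificity >= specificity
  if (!any(ok)) return(NA_real_)
  max(curve$sensitivity[ok])
}

#' Tanimoto baseline scores per fingerprint kind
#'
#' Scores the same pair table with each supplied fingerprint set, giving the
#' structural-similarity baselines that the DRS is compared against.
#'
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @param fingerprint_sets a single [fingerprint_set()] or (optionally
#'   named) list of them.
#' @return Named list of numeric score vectors, one per kind.
#' @export
fingerprint_baseline <- function(pairs, fingerprint_sets) {
  if (inherits(fingerprint_sets, "fingerprint_set"))
    fingerprint_sets <- list(fingerprint_sets)
  out <- lapply(fingerprint_sets, function(fps) pair_tanimoto(pairs, fps))
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- vapply(fingerprint_sets, function(f) f$kind, character(1))
  out
}

drug_domain_sets <- function(drugs, interactions, domain_map) {
  lapply(stats::setNames(drugs, drugs), function(d) {
    unique(unlist(domain_map$mapping[drug_targets(interactions, d)],
                  use.names = FALSE))
  })
}

#' Domain-matching ratio of negative pairs along the DRS
#'
#' Among negative pairs (no shared annotated target) scoring at or above
#' each threshold, the fraction whose two drugs have targets sharing at
#' least one protein domain. Rising ratios with rising score indicate that
#' high-scoring "negatives" tend to bind homologous pockets — candidate
#' unknown interactions. The unconditional fraction over all supplied pairs
#' is reported as the `"base_rate"` attribute (and equals the curve value at
#' any threshold at or below the minimum score).
#'
#' @param pairs data.frame of negative pairs (`drug_a`, `drug_b`).
#' @param scores DRS per pair row.
#' @param interactions an [interaction_map()] giving each drug's targets.
#' @param domain_map an [annotation_map()] of kind `"domain"`
#'   (target -> domain ids).
#' @param thresholds sweep values (default 201 evenly spaced in \[-1, 1\]).
#' @return data.frame `threshold`, `ratio` (NA where no pair reaches the
#'   threshold), `n_pairs`; attribute `"base_rate"`.
#' @export
domain_match_ratio <- function(pairs, scores, interactions, domain_map,
                               thresholds = seq(-1, 1, length.out = 201)) {
  stopifnot(inherits(domain_map, "annotation_map"))
  if (domain_map$kind != "domain") stop("domain_map must have kind 'domain'")
  if (nrow(pairs) != length(scores)) stop("pairs/scores length mismatch")
  dsets <- drug_domain_sets(unique(c(pairs$drug_a, pairs$drug_b)),
                            interactions, domain_map)
  match <- mapply(function(a, b) {
    da <- dsets[[a]]; db <- dsets[[b]]
    length(da) > 0 && length(db) > 0 && length(intersect(da, db)) > 0
  }, pairs$drug_a, pairs$drug_b, USE.NAMES = FALSE)
  out <- data.frame(
    threshold = thresholds,
    ratio = vapply(thresholds, function(t) {
      sel <- scores >= t
      if (!any(sel)) NA_real_ else mean(match[sel])
    }, numeric(1)),
    n_pairs = vapply(thresholds, function(t) sum(scores >= t), numeric(1)))
  attr(out, "base_rate") <- mean(match)
  out
}

atc_prefix_len <- function(level) {
  len <- c(`1` = 1L, `2` = 3L, `3` = 4L, `4` = 5L, `5` = 7L)[as.character(level)]
  if (is.na(len)) stop("unsupported ATC level: ", level)
  len
}

#' Do two drugs match at an ATC level?
#'
#' Codes match when any pair of codes agrees on the level's prefix
#' (level 1 = 1 character, level 2 = 3, level 3 = 4, level 4 = 5,
#' level 5 = 7).
#'
#' @param codes_a,codes_b character vectors of ATC codes.
#' @param level ATC level (default 2).
#' @export
atc_match <- function(codes_a, codes_b, level = 2) {
  len <- atc_prefix_len(level)
  a <- unique(substr(codes_a[nchar(codes_a) >= len], 1, len))
  b <- unique(substr(codes_b[nchar(codes_b) >= len], 1, len))
  length(intersect(a, b)) > 0
}

#' Mean ATC-matching partners by rank
#'
#' For each test drug, its partners are sorted by a similarity score and the
#' number of partners whose ATC code matches the drug's (at the requested
#' level) within the top `r` ranks is counted; the curve is the mean count
#' over test drugs at each rank. A steeper curve means the score places
#' pharmacologically similar drugs earlier.
#'
#' @param test_drugs drug ids evaluated.
#' @param partner_rankings named list (per test drug) of partner drug ids,
#'   best-scoring first.
#' @param atc_map an [annotation_map()] of kind `"atc"` (drug -> codes).
#' @param level ATC level, 2 or 3 (default 2).
#' @param max_rank deepest rank reported (default 20).
#' @return data.frame `rank`, `mean_matches` (monotone non-decreasing);
#'   attribute `"per_drug"` holds the per-drug match-count matrix.
#' @export
atc_match_curve <- function(test_drugs, partner_rankings, atc_map,
                            level = 2, max_rank = 20) {
  stopifnot(inherits(atc_map, "annotation_map"))
  if (atc_map$kind != "atc") stop("atc_map must have kind 'atc'")
  if (!level %in% c(1, 2, 3, 4, 5)) stop("level must be an ATC level 1-5")
  counts <- matrix(0, nrow = length(test_drugs), ncol = max_rank,
                   dimnames = list(test_drugs, NULL))
  for (d in test_drugs) {
    partners <- utils::head(partner_rankings[[d]], max_rank)
    if (is.null(partners)) stop("no ranking supplied for test drug ", d)
    hits <- vapply(partners, function(p)
      atc_match(atc_map$mapping[[d]] %||% character(0),
                atc_map$mapping[[p]] %||% character(0), level), logical(1))
    counts[d, ] <- cumsum(c(hits, rep(0, max_rank - length(hits))))[seq_len(max_rank)]
  }
  out <- data.frame(rank = seq_len(max_rank), mean_matches = colMeans(counts))
  attr(out, "per_drug") <- counts
  out
}

#' Per-group Pearson correlation between two scores
#'
#' @param scores_a,scores_b paired numeric vectors.
#' @param group_labels optional grouping; a single group when NULL.
#' @return data.frame `group`, `n`, `r`, `p`. Groups with fewer than 3
#'   pairs or a constant vector get NA with a warning.
#' @export
score_correlation <- function(scores_a, scores_b, group_labels = NULL) {
  if (length(scores_a) != length(scores_b)) stop("score length mismatch")
  if (is.null(group_labels)) group_labels <- rep("all", length(scores_a))
  groups <- unique(group_labels)
  res <- lapply(groups, function(g) {
    x <- scores_a[group_labels == g]
    y <- scores_b[group_labels == g]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("correlation undefined for group '", g,
              "' (too few pairs or constant scores)")
      return(data.frame(group = g, n = length(x), r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(group = g, n = length(x), r = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, res)
}
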