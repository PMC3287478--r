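# The DRS classifier: one probability Random Forest per negative sample set,
# all sharing the positive pairs and the [m | e] feature layout. The DRS of
# a pair is 2 * (mean positive-class vote fraction over the forests) - 1,
# hence bounded in [-1, 1] with 0 at classification parity. Internal
# validation uses a single classifier's out-of-bag votes (guaranteed unseen
# data); external validation holds out whole drugs.

#' Train the DRS Random Forest ensemble
#'
#' One probability forest per negative set, each trained on the common
#' positive pairs plus that set. Forests use standard Breiman defaults:
#' 500 trees, `mtry = floor(sqrt(2k))`, minimum node size 1, bootstrap
#' samples the size of the training set.
#'
#' @param positive_pairs data.frame of target-sharing pairs
#'   (`drug_a`, `drug_b`).
#' @param negative_sets list of sets from [sample_negative_sets()]; each
#'   must have exactly `nrow(positive_pairs)` pairs.
#' @param pc_scores projected drug matrix from [project()].
#' @param num_trees trees per forest (default 500).
#' @param mtry features tried per split; default `floor(sqrt(2k))`.
#' @param min_node_size minimum terminal node size (default 1).
#' @param seed integer; classifier `i` uses `seed + i` so forests differ
#'   even across identical negative sets, while the whole ensemble is
#'   reproducible.
#' @return Object of class `drs_ensemble`: `classifiers` (each holding the
#'   fitted forest plus its training pairs and labels), `k`,
#'   `feature_names`, `rf_params`, `manifest`.
#' @export
train_drs_ensemble <- function(positive_pairs, negative_sets, pc_scores,
                               num_trees = 500, mtry = NULL,
                               min_node_size = 1, seed = 1) {
  if (is.null(positive_pairs) || nrow(positive_pairs) == 0)
    stop("no positive pairs to train on")
  if (length(negative_sets) == 0) stop("no negative sets supplied")
  k <- ncol(pc_scores)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(2 * k)))
  feat_pos <- pair_feature_matrix(positive_pairs, pc_scores)
  classifiers <- vector("list", length(negative_sets))
  for (i in seq_along(negative_sets)) {
    set <- negative_sets[[i]]
    neg_pairs <- if (inherits(set, "negative_sample_set")) set$pairs else set
    if (nrow(neg_pairs) != nrow(positive_pairs))
      stop("negative set ", i, " has ", nrow(neg_pairs),
           " pairs; expected the positive count ", nrow(positive_pairs))
    feat_neg <- pair_feature_matrix(neg_pairs, pc_scores)
    df <- as.data.frame(rbind(feat_pos, feat_neg))
    df$.label <- factor(rep(c("positive", "negative"),
                            c(nrow(feat_pos), nrow(feat_neg))),
                        levels = c("negative", "positive"))
    rf <- ranger::ranger(dependent.variable.name = ".label", data = df,
                         probability = TRUE, num.trees = num_trees,
                         mtry = mtry, min.node.size = min_node_size,
                         seed = seed + i, num.threads = 1, verbose = FALSE)
    classifiers[[i]] <- list(
      model = rf,
      pairs = rbind(positive_pairs[, c("drug_a", "drug_b")],
                    neg_pairs[, c("drug_a", "drug_b")]),
      labels = as.character(df$.label))
  }
  structure(list(classifiers = classifiers, k = k,
                 feature_names = colnames(feat_pos),
                 rf_params = list(num_trees = num_trees, mtry = mtry,
                                  min_node_size = min_node_size),
                 manifest = list(seed = seed,
                                 n_positive = nrow(positive_pairs),
                                 n_sets = length(negative_sets),
                                 set_seeds = vapply(negative_sets, function(s)
                                   if (inherits(s, "negative_sample_set"))
                                     s$seed else NA_integer_, numeric(1)))),
            class = "drs_ensemble")
}

#' @export
print.drs_ensemble <- function(x, ...) {
  cat(sprintf("drs_ensemble: %d forests x %d trees over %d features (%d positive pairs)\n",
              length(x$classifiers), x$rf_params$num_trees,
              length(x$feature_names), x$manifest$n_positive))
  invisible(x)
}

score_feature_matrix <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "drs_ensemble"))
  if (ncol(features) != 2 * ensemble$k)
    stop("feature length ", ncol(features), " does not match 2k = ",
         2 * ensemble$k)
  df <- as.data.frame(features)
  colnames(df) <- ensemble$feature_names
  votes <- vapply(ensemble$classifiers, function(cl)
    stats::predict(cl$model, data = df, num.threads = 1,
                   verbose = FALSE)$predictions[, "positive"],
    numeric(nrow(df)))
  if (nrow(df) == 1) votes <- matrix(votes, nrow = 1)
  2 * rowMeans(votes) - 1
}

#' Score drug pairs with a trained ensemble
#'
#' The DRS is the mean positive-class vote fraction over the ensemble's
#' forests, rescaled to \[-1, 1\] (`2 p - 1`). Symmetric in pair order and
#' deterministic given the ensemble.
#'
#' @param ensemble a [train_drs_ensemble()] result.
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @param pc_scores projected drug matrix covering every pair member.
#' @return Numeric DRS vector, one value per pair row.
#' @export
score_pairs <- function(ensemble, pairs, pc_scores) {
  score_feature_matrix(ensemble, pair_feature_matrix(pairs, pc_scores))
}

#' Score one drug pair
#'
#' @inheritParams score_pairs
#' @param pc_a,pc_b projected component vectors of the two drugs.
#' @return A single DRS value in \[-1, 1\].
#' @export
score_pair <- function(ensemble, pc_a, pc_b) {
  v <- make_pair_vector(pc_a, pc_b)
  score_feature_matrix(ensemble, matrix(c(v$m, v$e), nrow = 1))
}

#' Rescale a DRS value to the unit interval
#'
#' Linear map `(drs + 1) / 2`, putting the score on the same 0-1 scale as a
#' Tanimoto similarity (so a raw DRS of 0.54 reads as 0.77).
#'
#' @param drs DRS value(s) in \[-1, 1\].
#' @export
rescale_unit <- function(drs) (drs + 1) / 2

#' Out-of-bag validation scores from one classifier
#'
#' For each training pair of the chosen classifier, the positive vote
#' fraction over only the trees whose bootstrap excluded that pair
#' (about one-third of trees), rescaled to \[-1, 1\]. Pairs that were never
#' out-of-bag (possible at very small tree counts) are omitted; their count
#' is recorded in the `"n_omitted"` attribute.
#'
#' @param ensemble a [train_drs_ensemble()] result.
#' @param which_classifier index of the classifier to read (default 1).
#' @return data.frame with `drug_a`, `drug_b`, `label`, `score`.
#' @export
oob_validation_scores <- function(ensemble, which_classifier = 1) {
  stopifnot(inherits(ensemble, "drs_ensemble"))
  if (which_classifier < 1 || which_classifier > length(ensemble$classifiers))
    stop("classifier index out of range: ", which_classifier)
  cl <- ensemble$classifiers[[which_classifier]]
  p <- cl$model$predictions[, "positive"]
  keep <- is.finite(p)
  out <- data.frame(cl$pairs[keep, , drop = FALSE],
                    label = cl$labels[keep],
                    score = 2 * p[keep] - 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_omitted") <- sum(!keep)
  if (any(!keep))
    message(sum(!keep), " pair(s) never out-of-bag were omitted")
  out
}

#' Split drugs into training and hold-out sets
#'
#' External validation removes whole drugs before training: every pair that
#' touches a held-out drug is excluded from the training pairs and forms the
#' external test set.
#'
#' @param drug_ids all drug ids.
#' @param n_holdout number of drugs to hold out (default 50).
#' @param seed integer seed; the same seed reproduces the split.
#' @return list with `train_drugs` and `test_drugs`.
#' @export
holdout_split <- function(drug_ids, n_holdout = 50, seed = 1) {
  drug_ids <- as.character(drug_ids)
  if (n_holdout >= length(drug_ids))
    stop("n_holdout must be smaller than the number of drugs")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- sort(sample(drug_ids, n_holdout))
  list(train_drugs = setdiff(sort(drug_ids), test), test_drugs = test)
}

#' Restrict a pair table to pairs within a drug set
#'
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @param drugs drug ids to keep.
#' @param touching if TRUE, keep pairs with at least one member in `drugs`
#'   (the external-test complement) instead of both members.
#' @export
pairs_within <- function(pairs, drugs, touching = FALSE) {
  inA <- pairs$drug_a %in% drugs
  inB <- pairs$drug_b %in% drugs
  pairs[if (touching) inA | inB else inA & inB, , drop = FALSE]
}
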