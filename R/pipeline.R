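# End-to-end convenience: clean -> PCA -> pairs -> labels -> under-sampled
# negatives -> forest ensemble, with an explicit training-drug universe so
# external hold-out validation is a one-liner.

#' Fit a DRS model end to end
#'
#' Runs the full training pipeline: descriptor cleaning, PCA to the variance
#' target, pair enumeration over the annotated training drugs, target-share
#' labelling, Tanimoto-based inverse-density under-sampling of the negative
#' pairs, and ensemble training. Drugs outside `train_drugs` (or without
#' target annotations) take no part in training but are still projected and
#' scoreable.
#'
#' @param descriptors a [descriptor_matrix()] over all drugs.
#' @param fingerprints a [fingerprint_set()] used for the similarity
#'   density of the negative pairs.
#' @param interactions an [interaction_map()].
#' @param train_drugs drugs eligible for training pairs; default all drugs
#'   in `descriptors`.
#' @param variance_target PCA variance target (default 0.9).
#' @param near_constant_frac cleaning threshold (default 0.9).
#' @param standardize z-score descriptors before PCA (default TRUE).
#' @param n_sets negative sample sets / forests (default 10).
#' @param num_trees trees per forest (default 500).
#' @param density_method,density_parameter similarity-density options, see
#'   [estimate_similarity_density()].
#' @param seed master seed driving sampling and forest construction.
#' @return list of class `drs_model`: `space` (the [fit_pc_space()] result),
#'   `pc_scores` (all drugs), `ensemble`, `train_pairs` (labelled),
#'   `negative_sets`, `train_drugs`, `seed`.
#' @export
drs_fit <- function(descriptors, fingerprints, interactions,
                    train_drugs = NULL, variance_target = 0.9,
                    near_constant_frac = 0.9, standardize = TRUE,
                    n_sets = 10, num_trees = 500,
                    density_method = "histogram", density_parameter = NULL,
                    seed = 1) {
  stopifnot(inherits(descriptors, "descriptor_matrix"),
            inherits(interactions, "interaction_map"))
  cleaned <- clean_descriptors(descriptors, near_constant_frac = near_constant_frac)
  space <- fit_pc_space(cleaned, variance_target = variance_target,
                        standardize = standardize)
  pc_scores <- project(cleaned, space)
  if (is.null(train_drugs)) train_drugs <- descriptors$drug_ids
  train_drugs <- intersect(train_drugs, names(interactions$drug_to_targets))
  if (length(train_drugs) < 3) stop("too few annotated training drugs")
  pairs <- label_pairs(enumerate_pairs(train_drugs), interactions)
  pos <- pairs[pairs$label == "positive", , drop = FALSE]
  neg <- pairs[pairs$label == "negative", , drop = FALSE]
  if (nrow(pos) == 0) stop("no positive (target-sharing) training pairs")
  if (nrow(neg) < nrow(pos))
    stop("fewer negative than positive pairs; cannot balance the sets")
  sims <- pair_tanimoto(neg, fingerprints)
  sets <- sample_negative_sets(neg, sims, set_size = nrow(pos),
                               n_sets = n_sets, seed = seed,
                               method = density_method,
                               parameter = density_parameter)
  ensemble <- train_drs_ensemble(pos, sets, pc_scores,
                                 num_trees = num_trees, seed = seed)
  structure(list(space = space, pc_scores = pc_scores, ensemble = ensemble,
                 train_pairs = pairs, negative_sets = sets,
                 train_drugs = train_drugs, seed = seed),
            class = "drs_model")
}

#' @export
print.drs_model <- function(x, ...) {
  cat(sprintf("drs_model: k = %d components, %d training drugs, %d positive pairs\n",
              x$space$k, length(x$train_drugs), x$ensemble$manifest$n_positive))
  print(x$ensemble)
  invisible(x)
}

#' Score pairs with a fitted DRS model
#'
#' @param model a [drs_fit()] result.
#' @param pairs data.frame with `drug_a`, `drug_b`; default every unordered
#'   pair of projected drugs.
#' @return The pair table with a `drs` column appended.
#' @export
drs_score <- function(model, pairs = NULL) {
  stopifnot(inherits(model, "drs_model"))
  if (is.null(pairs)) pairs <- enumerate_pairs(rownames(model$pc_scores))
  pairs$drs <- score_pairs(model$ensemble, pairs, model$pc_scores)
  pairs
}
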