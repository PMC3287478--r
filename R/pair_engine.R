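# Unordered drug pairs: enumeration, target-sharing labels, and the (M, E)
# pair encoding. M is the per-component mean of the two projected drugs
# (basal chemistry), E the per-component squared difference (chemical
# divergence); the classifier consumes the concatenation [m | e], which is
# invariant to the order of the drugs within a pair.

#' Enumerate all unordered drug pairs
#'
#' Canonical form: `drug_a < drug_b` lexicographically, rows sorted, no
#' self-pairs.
#'
#' @param drug_ids character vector of unique ids.
#' @return data.frame with columns `drug_a`, `drug_b` (`choose(n, 2)` rows).
#' @export
enumerate_pairs <- function(drug_ids) {
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(drug_ids)) stop("drug ids must be unique")
  if (length(drug_ids) < 2)
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      stringsAsFactors = FALSE))
  ids <- sort(drug_ids)
  cmb <- t(utils::combn(ids, 2L))
  data.frame(drug_a = cmb[, 1], drug_b = cmb[, 2], stringsAsFactors = FALSE)
}

#' Put a pair table into canonical order
#'
#' Swaps members so `drug_a < drug_b` within each row; other columns are
#' untouched.
#'
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @export
canonicalize_pairs <- function(pairs) {
  a <- pmin(pairs$drug_a, pairs$drug_b)
  b <- pmax(pairs$drug_a, pairs$drug_b)
  pairs$drug_a <- a
  pairs$drug_b <- b
  pairs
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Label drug pairs by target sharing
#'
#' `positive` if the two drugs share at least one annotated target,
#' `negative` if both drugs are annotated and their target sets are
#' disjoint, `unknown` if either drug has no interaction record (such pairs
#' are excluded from training but remain scoreable).
#'
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @param interactions an [interaction_map()].
#' @return The pair table with a `label` column added.
#' @export
label_pairs <- function(pairs, interactions) {
  stopifnot(inherits(interactions, "interaction_map"))
  annotated <- names(interactions$drug_to_targets)
  pos_keys <- unlist(lapply(interactions$target_to_drugs, function(ds) {
    if (length(ds) < 2) return(character(0))
    cmb <- utils::combn(ds, 2L)
    pair_key(cmb[1, ], cmb[2, ])
  }), use.names = FALSE)
  keys <- pair_key(pairs$drug_a, pairs$drug_b)
  known <- pairs$drug_a %in% annotated & pairs$drug_b %in% annotated
  label <- ifelse(!known, "unknown",
                  ifelse(keys %in% pos_keys, "positive", "negative"))
  pairs$label <- label
  pairs
}

#' Label one drug pair
#'
#' @param drug_a,drug_b drug ids.
#' @inheritParams label_pairs
#' @return `"positive"`, `"negative"` or `"unknown"`.
#' @export
label_pair <- function(drug_a, drug_b, interactions) {
  stopifnot(inherits(interactions, "interaction_map"))
  ta <- interactions$drug_to_targets[[drug_a]]
  tb <- interactions$drug_to_targets[[drug_b]]
  if (is.null(ta) || is.null(tb)) return("unknown")
  if (length(intersect(ta, tb)) > 0) "positive" else "negative"
}

#' Encode one drug pair as its (M, E) vectors
#'
#' `m[i] = (a[i] + b[i]) / 2` and `e[i] = (a[i] - b[i])^2`, computed
#' per principal component. Symmetric in its arguments.
#'
#' @param pc_a,pc_b numeric vectors of equal length (projected drugs).
#' @return list with numeric vectors `m` and `e`.
#' @export
make_pair_vector <- function(pc_a, pc_b) {
  if (length(pc_a) != length(pc_b))
    stop("projected drug vectors differ in length")
  list(m = (pc_a + pc_b) / 2, e = (pc_a - pc_b)^2)
}

#' Build the classifier feature matrix for a pair table
#'
#' One row per pair: the concatenation `[m_1..m_k, e_1..e_k]`.
#'
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @param pc_scores numeric matrix of projected drugs (rows named by drug
#'   id), as returned by [project()].
#' @return numeric matrix (pairs x 2k).
#' @export
pair_feature_matrix <- function(pairs, pc_scores) {
  missing <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), rownames(pc_scores))
  if (length(missing))
    stop("drug(s) absent from the projected score matrix: ",
         paste(missing, collapse = ", "))
  A <- pc_scores[pairs$drug_a, , drop = FALSE]
  B <- pc_scores[pairs$drug_b, , drop = FALSE]
  k <- ncol(pc_scores)
  out <- cbind((A + B) / 2, (A - B)^2)
  colnames(out) <- c(paste0("m_", seq_len(k)), paste0("e_", seq_len(k)))
  rownames(out) <- NULL
  out
}
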