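# Descriptor cleaning and the principal-component drug representation.
# Cleaning drops error-flagged and near-constant descriptors; PCA (SVD on the
# standardized matrix) keeps the minimal number of components reaching the
# variance target. A fixed sign convention keeps loadings reproducible.

#' Drop erroneous and near-constant descriptors
#'
#' Removes (a) descriptors with any missing/error-flagged cell and (b)
#' descriptors whose modal value occurs in strictly more than
#' `near_constant_frac` of the drugs — uninformative, almost-constant
#' columns. The rule is strictly greater-than: a modal value covering exactly
#' the threshold fraction is kept. Idempotent.
#'
#' @param D a [descriptor_matrix()].
#' @param near_constant_frac fraction of drugs above which a shared modal
#'   value disqualifies a descriptor (default 0.9).
#' @return A [descriptor_matrix()] over the surviving columns. The attribute
#'   `"dropped"` is a data.frame of `name` and `reason`
#'   (`"error"`/`"near_constant"`).
#' @export
clean_descriptors <- function(D, near_constant_frac = 0.9) {
  stopifnot(inherits(D, "descriptor_matrix"))
  if (ncol(D$values) == 0) stop("descriptor matrix has no columns")
  n <- nrow(D$values)
  has_error <- colSums(D$missing_mask) > 0
  modal_count <- apply(D$values, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(n)  # fully-missing column; dropped as error anyway
    max(table(col))
  })
  near_const <- (modal_count / n) > near_constant_frac
  drop <- has_error | near_const
  reason <- ifelse(has_error, "error", "near_constant")[drop]
  if (all(drop))
    stop("all descriptors dropped during cleaning")
  out <- descriptor_matrix(D$values[, !drop, drop = FALSE],
                           drug_ids = D$drug_ids,
                           descriptor_names = D$descriptor_names[!drop],
                           missing_mask = D$missing_mask[, !drop, drop = FALSE])
  attr(out, "dropped") <- data.frame(name = D$descriptor_names[drop],
                                     reason = reason,
                                     stringsAsFactors = FALSE)
  out
}

#' Fit the principal-component drug representation
#'
#' SVD-based PCA on the (optionally z-scored) descriptor matrix. The number
#' of components `k` is the smallest for which the cumulative explained
#' variance reaches `variance_target`. Loadings follow a deterministic sign
#' convention (the largest-magnitude element of each loading column is
#' positive) so fits are reproducible across platforms.
#'
#' @param D a cleaned [descriptor_matrix()] (no missing cells, no constant
#'   columns), at least 2 drugs.
#' @param variance_target fraction of total variance to retain, in (0, 1].
#'   Default 0.9.
#' @param standardize z-score each descriptor before the SVD (default TRUE).
#'   Descriptor scales typically differ by orders of magnitude; without
#'   standardization the widest-ranged descriptors dominate the components.
#' @return Object of class `pc_space`: `descriptor_names_used`, `center`,
#'   `scale`, `loadings` (descriptors x k), `explained_fraction` (length k),
#'   `k`, `variance_target`, `standardize`.
#' @export
fit_pc_space <- function(D, variance_target = 0.9, standardize = TRUE) {
  stopifnot(inherits(D, "descriptor_matrix"))
  if (!is.numeric(variance_target) || length(variance_target) != 1 ||
      variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  if (any(D$missing_mask) || anyNA(D$values))
    stop("descriptor matrix still has missing cells; run clean_descriptors() first")
  n <- nrow(D$values)
  if (n < 2) stop("need at least 2 drugs to fit a component space")
  center <- colMeans(D$values)
  scl <- if (standardize) apply(D$values, 2, stats::sd) else rep(1, ncol(D$values))
  if (any(scl == 0))
    stop("zero-variance descriptor column(s); run clean_descriptors() first")
  X <- scale(D$values, center = center, scale = scl)
  s <- svd(X)
  ev <- s$d^2
  explained <- ev / sum(ev)
  k <- which(cumsum(explained) >= variance_target - 1e-12)[1]
  loadings <- s$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|x| element of each column positive
  for (j in seq_len(k)) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- D$descriptor_names
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(descriptor_names_used = D$descriptor_names,
                 center = stats::setNames(center, D$descriptor_names),
                 scale = stats::setNames(scl, D$descriptor_names),
                 loadings = loadings,
                 explained_fraction = explained[seq_len(k)],
                 k = k,
                 variance_target = variance_target,
                 standardize = standardize,
                 schema_version = 1L),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("pc_space: %d components over %d descriptors (%.1f%% variance, target %.0f%%)\n",
              x$k, length(x$descriptor_names_used),
              100 * sum(x$explained_fraction), 100 * x$variance_target))
  invisible(x)
}

#' Project drugs into a fitted component space
#'
#' Centers/scales the required descriptor columns and multiplies by the
#' loadings. Columns beyond those used by the fit are ignored; a missing
#' required column is an error naming it.
#'
#' @param D a [descriptor_matrix()] containing every descriptor the space
#'   was fitted on.
#' @param space a [fit_pc_space()] result.
#' @return Numeric matrix (drugs x k) with drug ids as row names.
#' @export
project <- function(D, space) {
  stopifnot(inherits(D, "descriptor_matrix"), inherits(space, "pc_space"))
  need <- space$descriptor_names_used
  absent <- setdiff(need, D$descriptor_names)
  if (length(absent))
    stop("descriptor column(s) required by the component space are missing: ",
         paste(absent, collapse = ", "))
  vals <- D$values[, need, drop = FALSE]
  if (anyNA(vals))
    stop("missing values in descriptors required for projection")
  X <- sweep(sweep(vals, 2, space$center[need], "-"), 2, space$scale[need], "/")
  scores <- X %*% space$loadings
  rownames(scores) <- D$drug_ids
  scores
}
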