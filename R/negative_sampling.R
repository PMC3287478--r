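# Structural-similarity-aware under-sampling of the negative (no shared
# target) class. Negative pairs vastly outnumber positives, and naive uniform
# sampling over-represents the bulk of mutually dissimilar pairs; drawing
# with probability inversely proportional to the density of each pair's
# Tanimoto similarity yields structurally diverse negative sets. Ten
# independent sets feed the ten-classifier ensemble.

#' Tanimoto coefficient of two binary fingerprints
#'
#' Shared on-bits over union on-bits. Two all-zero fingerprints have an
#' undefined 0/0 ratio; by convention the score is 0.
#'
#' @param fp_a,fp_b 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprint lengths differ")
  if (!all(fp_a %in% c(0, 1)) || !all(fp_b %in% c(0, 1)))
    stop("fingerprints must be 0/1 vectors")
  u <- sum(fp_a | fp_b)
  if (u == 0) return(0)
  sum(fp_a & fp_b) / u
}

#' Tanimoto similarity for a table of drug pairs
#'
#' Vectorized over the rows of a pair table against one fingerprint set.
#'
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @param fps a [fingerprint_set()] covering every pair member.
#' @return Numeric vector of similarities, one per row.
#' @export
pair_tanimoto <- function(pairs, fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  missing <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), fps$drug_ids)
  if (length(missing))
    stop("drug(s) absent from the fingerprint set: ",
         paste(missing, collapse = ", "))
  A <- fps$bits[pairs$drug_a, , drop = FALSE]
  B <- fps$bits[pairs$drug_b, , drop = FALSE]
  inter <- unname(rowSums(A * B))
  union <- unname(rowSums((A + B) > 0))
  ifelse(union == 0, 0, inter / union)
}

#' Estimate the density of pairwise structural similarities
#'
#' Normalized density over \[0, 1\] of the negative pairs' Tanimoto
#' similarities. A small positive floor (`1 / (10 n)`) is added before
#' normalization so regions with no observed mass still have finite density
#' — inverse-density sampling weights then stay bounded. Histogram (50 equal
#' bins, the default) or Gaussian KDE (Silverman bandwidth) estimators.
#'
#' @param similarities numeric vector in \[0, 1\].
#' @param method `"histogram"` or `"kde"`.
#' @param parameter bins for the histogram (default 50), bandwidth for the
#'   KDE (default Silverman's rule).
#' @return Object of class `similarity_density`: `grid`, `density`
#'   (masses summing to 1 over the grid), `method`, `bandwidth_or_bins`,
#'   `floor`, and for histograms `breaks`.
#' @export
estimate_similarity_density <- function(similarities,
                                        method = c("histogram", "kde"),
                                        parameter = NULL) {
  method <- match.arg(method)
  if (length(similarities) == 0) stop("no similarities supplied")
  if (anyNA(similarities) || any(similarities < 0 | similarities > 1))
    stop("similarities must lie in [0, 1]")
  n <- length(similarities)
  eps <- 1 / (10 * n)
  if (method == "histogram") {
    bins <- if (is.null(parameter)) 50L else as.integer(parameter)
    stopifnot(bins >= 1)
    breaks <- seq(0, 1, length.out = bins + 1)
    idx <- pmin(pmax(findInterval(similarities, breaks, rightmost.closed = TRUE), 1L),
                bins)
    mass <- tabulate(idx, nbins = bins) / n + eps
    mass <- mass / sum(mass)
    structure(list(grid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
                   density = mass, method = method,
                   bandwidth_or_bins = bins, floor = eps, breaks = breaks),
              class = "similarity_density")
  } else {
    bw <- if (is.null(parameter)) stats::bw.nrd0(similarities) else parameter
    if (!is.finite(bw) || bw <= 0) bw <- 0.05  # degenerate (constant) input
    grid <- seq(0, 1, length.out = 512)
    d <- stats::density(similarities, bw = bw, from = 0, to = 1, n = 512)
    mass <- d$y / sum(d$y) + eps
    mass <- mass / sum(mass)
    structure(list(grid = grid, density = mass, method = method,
                   bandwidth_or_bins = bw, floor = eps),
              class = "similarity_density")
  }
}

#' Evaluate a similarity density
#'
#' @param sd_obj a [estimate_similarity_density()] result.
#' @param x similarity values in \[0, 1\].
#' @return Density mass at each `x` (strictly positive).
#' @export
density_at <- function(sd_obj, x) {
  stopifnot(inherits(sd_obj, "similarity_density"))
  if (any(x < 0 | x > 1)) stop("similarity values must lie in [0, 1]")
  if (sd_obj$method == "histogram") {
    bins <- sd_obj$bandwidth_or_bins
    idx <- pmin(pmax(findInterval(x, sd_obj$breaks, rightmost.closed = TRUE), 1L),
                bins)
    sd_obj$density[idx]
  } else {
    stats::approx(sd_obj$grid, sd_obj$density, xout = x, rule = 2)$y
  }
}

#' Draw inverse-density negative sample sets
#'
#' Each set is drawn without replacement, with per-pair weight proportional
#' to `1 / density(similarity)`; sets are drawn independently of one another
#' (they may overlap across sets, never within one). Sized to the positive
#' count, they balance each classifier's training data while favouring pairs
#' from sparsely populated similarity regions.
#'
#' @param negative_pairs data.frame of negative pairs (`drug_a`, `drug_b`).
#' @param similarities Tanimoto similarity per row of `negative_pairs`.
#' @param set_size pairs per set (use the positive-pair count).
#' @param n_sets number of sets (default 10).
#' @param seed integer seed; the draw is fully reproducible from it.
#' @param density optional precomputed [estimate_similarity_density()]
#'   object; fitted from `similarities` when NULL.
#' @param method,parameter passed to [estimate_similarity_density()] when
#'   fitting.
#' @return List of `negative_sample_set` objects, each with `pairs`,
#'   `indices`, `seed`, `set_index`.
#' @export
sample_negative_sets <- function(negative_pairs, similarities, set_size,
                                 n_sets = 10, seed = 1, density = NULL,
                                 method = "histogram", parameter = NULL) {
  n <- nrow(negative_pairs)
  if (length(similarities) != n)
    stop("similarities must align with negative_pairs rows")
  if (set_size > n)
    stop("set_size (", set_size, ") exceeds available negative pairs (", n, ")")
  if (is.null(density))
    density <- estimate_similarity_density(similarities, method = method,
                                           parameter = parameter)
  w <- 1 / density_at(density, similarities)
  w <- w / sum(w)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    idx <- sample.int(n, set_size, replace = FALSE, prob = w)
    structure(list(pairs = negative_pairs[idx, , drop = FALSE],
                   indices = idx, seed = seed, set_index = i),
              class = "negative_sample_set")
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
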