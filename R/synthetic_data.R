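# Self-contained synthetic drug-target benchmark. The generator plants the
# statistical structure the DRS relies on: drugs binding a common target
# cluster in descriptor space; fingerprints are noisy projections of the
# descriptors (informative but imperfect Tanimoto); targets grouped into
# shared-domain families sit near each other, so some chemically similar
# pairs share a domain but no target; ATC codes follow the target clusters.
# A promiscuity fraction adds cross-cluster bindings whose descriptors do
# NOT move toward the extra target, creating the structurally dissimilar
# common-target pairs that defeat plain structural similarity.

#' Configuration for the synthetic benchmark generator
#'
#' Defaults define the package's standard study conditions: 200 drugs, 20
#' targets, 60 descriptors, 128 fingerprint bits, tight within-target spread
#' (`cluster_sd` 0.3) against unit background spread (`noise_sd` 1.0).
#'
#' @param n_drugs,n_targets,n_descriptors,n_bits dataset dimensions.
#' @param cluster_sd within-target descriptor spread; must stay below
#'   `noise_sd` for a learnable signal regime.
#' @param noise_sd background spread of target-family centroids.
#' @param mean_targets_per_drug mean of the shifted-Poisson drug degree
#'   (every drug binds at least one target); default 1.5.
#' @param domain_groups targets per shared-domain family (default 2).
#' @param domain_sd within-family spread of target centroids (default
#'   0.25): same-family targets are chemically adjacent, so their binders
#'   form close but target-disjoint pairs.
#' @param promiscuity fraction of drugs additionally binding one target
#'   from a foreign domain family (default 0.1).
#' @param fingerprint_noise_sd noise added to the random bit projections
#'   (default 1.0); larger values decorrelate Tanimoto from descriptor
#'   proximity.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 200, n_targets = 20, n_descriptors = 60,
                             n_bits = 128, cluster_sd = 0.3, noise_sd = 1.0,
                             mean_targets_per_drug = 1.5, domain_groups = 2,
                             domain_sd = 0.25, promiscuity = 0.1,
                             fingerprint_noise_sd = 1.0, seed = 7) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
              n_descriptors = as.integer(n_descriptors), n_bits = as.integer(n_bits),
              cluster_sd = cluster_sd, noise_sd = noise_sd,
              mean_targets_per_drug = mean_targets_per_drug,
              domain_groups = as.integer(domain_groups), domain_sd = domain_sd,
              promiscuity = promiscuity,
              fingerprint_noise_sd = fingerprint_noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_drugs, n_targets, n_descriptors, n_bits, domain_groups) <= 0))
      stop("all counts must be positive")
    if (cluster_sd >= noise_sd)
      stop("cluster_sd must be below noise_sd for a learnable signal regime")
    if (mean_targets_per_drug < 1)
      stop("mean_targets_per_drug must be at least 1")
    if (promiscuity < 0 || promiscuity > 1) stop("promiscuity must be in [0, 1]")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic drug-target dataset bundle
#'
#' Targets are partitioned into shared-domain families; each family gets a
#' centroid (iid normal, sd `noise_sd`) and each target sits at a small
#' offset (sd `domain_sd`) from its family centroid. Each drug binds
#' `1 + Poisson(mean - 1)` targets and its descriptors are drawn around the
#' mean of those targets' centroids with sd `cluster_sd`. A `promiscuity`
#' fraction of drugs then gains one extra target from a different family
#' without moving in descriptor space. Fingerprint bits threshold noisy
#' random projections of the descriptors. Domain ids are shared within each
#' family; every drug carries one ATC code per bound primary target, with
#' the level-2 prefix identifying the family and the level-3 character the
#' target, so pharmacological similarity follows the planted clusters.
#' Bitwise reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_bundle`: `descriptors`
#'   ([descriptor_matrix()]), `fingerprints` ([fingerprint_set()]),
#'   `interactions` ([interaction_map()]), `domains` and `atc`
#'   ([annotation_map()]s), `truth` (target assignments, centroids,
#'   families, promiscuous drug ids, projection matrix), `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  d <- config$n_descriptors
  drug_ids <- sprintf("SD%04d", seq_len(config$n_drugs))
  target_ids <- sprintf("T%03d", seq_len(config$n_targets))

  # domain families and target centroids
  family <- ((seq_len(config$n_targets) - 1) %/% config$domain_groups) + 1L
  n_fam <- max(family)
  fam_centroid <- matrix(stats::rnorm(n_fam * d, 0, config$noise_sd), nrow = n_fam)
  centroid <- fam_centroid[family, , drop = FALSE] +
    matrix(stats::rnorm(config$n_targets * d, 0, config$domain_sd),
           nrow = config$n_targets)
  rownames(centroid) <- target_ids

  # primary target assignment (shifted Poisson degree)
  degree <- 1L + stats::rpois(config$n_drugs, config$mean_targets_per_drug - 1)
  degree <- pmin(degree, config$n_targets)
  primary <- lapply(degree, function(k) sort(sample.int(config$n_targets, k)))

  # descriptors around the mean of the primary targets' centroids
  mu <- t(vapply(primary, function(tg)
    colMeans(centroid[tg, , drop = FALSE]), numeric(d)))
  values <- mu + matrix(stats::rnorm(config$n_drugs * d, 0, config$cluster_sd),
                        nrow = config$n_drugs)
  colnames(values) <- sprintf("desc_%03d", seq_len(d))
  descriptors <- descriptor_matrix(values, drug_ids = drug_ids)

  # promiscuous drugs: one extra target from a foreign family, descriptors
  # unchanged -> structurally dissimilar positive pairs
  n_prom <- round(config$promiscuity * config$n_drugs)
  promiscuous <- if (n_prom > 0) sort(sample.int(config$n_drugs, n_prom)) else integer(0)
  assignment <- primary
  for (i in promiscuous) {
    foreign <- which(!family %in% family[primary[[i]]])
    if (length(foreign))
      assignment[[i]] <- sort(c(primary[[i]], sample(foreign, 1)))
  }
  interactions <- interaction_map(
    stats::setNames(lapply(assignment, function(tg) target_ids[tg]), drug_ids))

  # fingerprints: thresholded noisy random projections of the descriptors
  W <- matrix(stats::rnorm(config$n_bits * d, 0, 1 / sqrt(d)), nrow = d)
  raw <- values %*% W +
    matrix(stats::rnorm(config$n_drugs * config$n_bits, 0,
                        config$fingerprint_noise_sd),
           nrow = config$n_drugs)
  bits <- (raw > 0) * 1L
  colnames(bits) <- sprintf("bit_%03d", seq_len(config$n_bits))
  fingerprints <- fingerprint_set(bits, drug_ids = drug_ids,
                                  kind = "synthetic-projection")

  # domains: one shared id per family
  domains <- annotation_map(
    stats::setNames(lapply(seq_len(config$n_targets),
                           function(t) sprintf("PF%05d", family[t])),
                    target_ids),
    kind = "domain")

  # ATC: family fixes the level-2 prefix, target the level-3 character
  target_atc <- vapply(seq_len(config$n_targets), function(t) {
    within <- ((t - 1) %% config$domain_groups) + 1L
    sprintf("%s%02d%s%s%02d",
            LETTERS[((family[t] - 1) %% 26) + 1],
            family[t] %% 100,
            LETTERS[((within - 1) %% 26) + 1],
            "A", t %% 100)
  }, character(1))
  atc <- annotation_map(
    stats::setNames(lapply(primary, function(tg) unique(target_atc[tg])), drug_ids),
    kind = "atc")

  structure(list(descriptors = descriptors, fingerprints = fingerprints,
                 interactions = interactions, domains = domains, atc = atc,
                 truth = list(assignment = stats::setNames(
                                lapply(assignment, function(tg) target_ids[tg]),
                                drug_ids),
                              primary = stats::setNames(
                                lapply(primary, function(tg) target_ids[tg]),
                                drug_ids),
                              centroids = centroid,
                              family = stats::setNames(family, target_ids),
                              target_atc = stats::setNames(target_atc, target_ids),
                              promiscuous = drug_ids[promiscuous],
                              projection = W),
                 config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("synthetic_bundle: %d drugs, %d targets, %d descriptors, %d bits (seed %d)\n",
              x$config$n_drugs, x$config$n_targets, x$config$n_descriptors,
              x$config$n_bits, x$config$seed))
  invisible(x)
}

#' Write a synthetic bundle to a directory of standard tables
#'
#' Produces the five tabular inputs (`descriptors.tsv`, `fingerprints.tsv`,
#' `interactions.tsv`, `domains.tsv`, `atc.tsv`) plus `truth.json`.
#'
#' @param bundle a [generate_synthetic()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_descriptor_table(bundle$descriptors, file.path(dir, "descriptors.tsv"))
  write_fingerprints(bundle$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_interactions(bundle$interactions, file.path(dir, "interactions.tsv"))
  write_annotations(bundle$domains, file.path(dir, "domains.tsv"))
  write_annotations(bundle$atc, file.path(dir, "atc.tsv"))
  jsonlite::write_json(
    list(config = unclass(bundle$config),
         assignment = bundle$truth$assignment,
         family = as.list(bundle$truth$family),
         promiscuous = bundle$truth$promiscuous),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
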