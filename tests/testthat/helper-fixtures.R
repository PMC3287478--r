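# Shared fixtures, built once per test run and cached. The "small" bundle
# and model keep per-file tests fast; the full-preset model used by the
# acceptance checks is built lazily only when those tests run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_config <- function(...) {
  synthetic_config(n_drugs = 80, n_targets = 10, n_descriptors = 40,
                   n_bits = 64, seed = 11, ...)
}

small_bundle <- function() cached("small_bundle", function() {
  generate_synthetic(small_config())
})

small_model <- function() cached("small_model", function() {
  b <- small_bundle()
  drs_fit(b$descriptors, b$fingerprints, b$interactions,
          n_sets = 4, num_trees = 150, seed = 5)
})

# all pairs of the small bundle, labelled and DRS-scored
small_scored_pairs <- function() cached("small_scored_pairs", function() {
  b <- small_bundle()
  drs_score(small_model(), label_pairs(enumerate_pairs(b$descriptors$drug_ids),
                                       b$interactions))
})

# the default study conditions used by the acceptance checks: 200 drugs,
# 20 targets, 10 forests x 200 trees, 50-drug external hold-out
preset_bundle <- function() cached("preset_bundle", function() {
  generate_synthetic(synthetic_config())
})

preset_split <- function() cached("preset_split", function() {
  holdout_split(preset_bundle()$descriptors$drug_ids, 50, seed = 3)
})

preset_holdout_model <- function() cached("preset_holdout_model", function() {
  b <- preset_bundle()
  drs_fit(b$descriptors, b$fingerprints, b$interactions,
          train_drugs = preset_split()$train_drugs,
          n_sets = 10, num_trees = 200, seed = 11)
})

preset_full_model <- function() cached("preset_full_model", function() {
  b <- preset_bundle()
  drs_fit(b$descriptors, b$fingerprints, b$interactions,
          n_sets = 10, num_trees = 200, seed = 11)
})

preset_full_scored <- function() cached("preset_full_scored", function() {
  b <- preset_bundle()
  drs_score(preset_full_model(),
            label_pairs(enumerate_pairs(b$descriptors$drug_ids),
                        b$interactions))
})

# partner drugs of `drug` in `pairs`, best score first
rank_partners <- function(pairs, score, drug) {
  sel <- pairs$drug_a == drug | pairs$drug_b == drug
  partner <- ifelse(pairs$drug_a[sel] == drug, pairs$drug_b[sel],
                    pairs$drug_a[sel])
  partner[order(-score[sel])]
}

write_tsv_fixture <- function(lines, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}
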