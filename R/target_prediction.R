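# Target transfer: a query drug inherits candidate targets from database
# drugs via the DRS. Each target's score is the maximum DRS between the
# query and any database drug annotated with it; ties are broken by how many
# of those drugs score above a fixed threshold (0.5), then lexicographically.
# Evidence is optionally split into drugs that share a known target with the
# query ("shared_target") and drugs that do not ("new_prediction"), so that
# genuinely new predictions can be judged separately.

#' DRS of a query drug against a set of database drugs
#'
#' @param query drug id present in `pc_scores`.
#' @param database_drugs drug ids to score against (the query itself is
#'   dropped if present).
#' @param ensemble a [train_drs_ensemble()] result.
#' @param pc_scores projected drug matrix covering query and database.
#' @return Named numeric vector of DRS values, one per database drug.
#' @export
query_database_scores <- function(query, database_drugs, ensemble, pc_scores) {
  if (!query %in% rownames(pc_scores))
    stop("query drug absent from the projected feature space: ", query)
  database_drugs <- setdiff(database_drugs, query)
  pairs <- data.frame(drug_a = query, drug_b = database_drugs,
                      stringsAsFactors = FALSE)
  stats::setNames(score_pairs(ensemble, pairs, pc_scores), database_drugs)
}

rank_target_table <- function(evidence, tie_threshold, source) {
  # evidence: data.frame(target_id, drs) with one row per (target, drug) link
  if (nrow(evidence) == 0)
    return(data.frame(target_id = character(0), score = numeric(0),
                      frequency = integer(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  sc <- tapply(evidence$drs, evidence$target_id, max)
  fr <- tapply(evidence$drs > tie_threshold, evidence$target_id, sum)
  tab <- data.frame(target_id = names(sc), score = as.numeric(sc),
                    frequency = as.integer(fr), source = source,
                    stringsAsFactors = FALSE)
  ord <- order(-tab$score, -tab$frequency, tab$target_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Rank candidate targets for a query drug
#'
#' Transfers the DRS from annotated database drugs to their targets:
#' `score(t) = max` DRS between the query and any drug binding `t`;
#' `frequency(t)` counts the binding drugs whose DRS exceeds
#' `tie_threshold`. Rows sort by score, then frequency, then target id.
#' With `split_by_source = TRUE` two tables are returned: one ranked from
#' evidence drugs sharing at least one known target with the query, one from
#' drugs sharing none (new predictions).
#'
#' @param query drug id.
#' @param scores named DRS vector over database drugs, e.g. from
#'   [query_database_scores()].
#' @param interactions an [interaction_map()] annotating the database drugs
#'   (and, for the source split, possibly the query).
#' @param tie_threshold DRS above which an evidence drug counts toward the
#'   tie-break frequency (default 0.5).
#' @param split_by_source return separate shared-target / new-prediction
#'   tables (default TRUE).
#' @param query_targets known targets of the query used for the source
#'   split; defaults to the query's entry in `interactions`. Irrelevant when
#'   `split_by_source = FALSE`.
#' @return A `target_score_table` data.frame (`target_id`, `score`,
#'   `frequency`, `source`, `rank`), or when split a list with elements
#'   `shared_target` and `new_prediction`.
#' @export
predict_targets <- function(query, scores, interactions, tie_threshold = 0.5,
                            split_by_source = TRUE, query_targets = NULL) {
  stopifnot(inherits(interactions, "interaction_map"))
  db <- setdiff(intersect(names(scores), names(interactions$drug_to_targets)),
                query)
  evidence <- data.frame(
    drug = rep(db, lengths(interactions$drug_to_targets[db])),
    target_id = unlist(interactions$drug_to_targets[db], use.names = FALSE),
    stringsAsFactors = FALSE)
  evidence$drs <- unname(scores[evidence$drug])
  if (!split_by_source)
    return(rank_target_table(evidence, tie_threshold, "all"))
  if (is.null(query_targets)) query_targets <- drug_targets(interactions, query)
  shares <- vapply(interactions$drug_to_targets[db],
                   function(tg) length(intersect(tg, query_targets)) > 0,
                   logical(1))
  shared_drugs <- db[shares]
  list(
    shared_target = rank_target_table(
      evidence[evidence$drug %in% shared_drugs, , drop = FALSE],
      tie_threshold, "shared_target"),
    new_prediction = rank_target_table(
      evidence[!evidence$drug %in% shared_drugs, , drop = FALSE],
      tie_threshold, "new_prediction"))
}

#' Known-target recovery under leave-one-drug-out
#'
#' For each annotated drug in turn, the drug is removed from the database
#' (so it cannot supply its own annotation) and its targets are re-ranked
#' from the remaining drugs' annotations via [predict_targets()]. The curve
#' reports, for each rank `r`, the fraction of drugs with at least one known
#' target at rank `r` or better.
#'
#' @param interactions an [interaction_map()].
#' @param pair_scores data.frame `drug_a`, `drug_b`, `drs` covering all
#'   pairs among the evaluated drugs (e.g. every enumerated pair scored with
#'   [score_pairs()]).
#' @param max_rank deepest rank reported (default 10).
#' @param source which evidence table to scan: `"shared_target"` (default),
#'   `"new_prediction"`, or `"all"` (no source split).
#' @param tie_threshold passed to [predict_targets()].
#' @param drugs optionally restrict the evaluated queries.
#' @return data.frame `rank`, `success_rate` (monotone non-decreasing), with
#'   attribute `"n_drugs"`. Empty with a warning when fewer than 2 annotated
#'   drugs are available.
#' @export
known_target_recovery <- function(interactions, pair_scores, max_rank = 10,
                                  source = c("shared_target", "new_prediction", "all"),
                                  tie_threshold = 0.5, drugs = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(interactions, "interaction_map"))
  annotated <- names(interactions$drug_to_targets)
  queries <- if (is.null(drugs)) annotated else intersect(drugs, annotated)
  if (length(annotated) < 2) {
    warning("need at least 2 annotated drugs for leave-one-drug-out recovery")
    return(data.frame(rank = integer(0), success_rate = numeric(0)))
  }
  lookup <- new.env(parent = emptyenv())
  assign_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keys <- assign_key(pair_scores$drug_a, pair_scores$drug_b)
  drs_by_key <- stats::setNames(pair_scores$drs, keys)
  first_rank <- vapply(queries, function(q) {
    db <- setdiff(annotated, q)
    sc <- drs_by_key[assign_key(q, db)]
    names(sc) <- db
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0) return(NA_real_)
    res <- predict_targets(q, sc, interactions, tie_threshold = tie_threshold,
                           split_by_source = source != "all")
    tab <- if (source == "all") res else res[[source]]
    hit <- tab$rank[tab$target_id %in% drug_targets(interactions, q)]
    if (length(hit) == 0) Inf else min(hit)
  }, numeric(1))
  first_rank <- first_rank[!is.na(first_rank)]
  out <- data.frame(rank = seq_len(max_rank),
                    success_rate = vapply(seq_len(max_rank),
                                          function(r) mean(first_rank <= r),
                                          numeric(1)))
  attr(out, "n_drugs") <- length(first_rank)
  out
}
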