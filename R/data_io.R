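# Tabular readers/writers for the five input kinds: descriptor matrices,
# fingerprint bit matrices, drug-target interactions, and domain/ATC
# annotation maps. drug_id is always the first column; delimiter follows the
# file extension (.csv -> comma, everything else tab) unless given.

detect_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Construct a descriptor matrix
#'
#' A `descriptor_matrix` holds drugs (rows) by numeric chemical descriptors
#' (columns) plus a logical mask marking cells that were missing or
#' non-numeric in the source. Masked cells are kept as `NA`, never silently
#' zeroed; [clean_descriptors()] decides their fate.
#'
#' @param values numeric matrix, drugs by descriptors.
#' @param drug_ids character vector of unique row identifiers.
#' @param descriptor_names character vector of unique column names.
#' @param missing_mask logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @return An object of class `descriptor_matrix` with fields `drug_ids`,
#'   `descriptor_names`, `values`, `missing_mask`.
#' @export
descriptor_matrix <- function(values, drug_ids = rownames(values),
                              descriptor_names = colnames(values),
                              missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  drug_ids <- as.character(drug_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(drug_ids) != nrow(values))
    stop("drug_ids length does not match row count")
  if (length(descriptor_names) != ncol(values))
    stop("descriptor_names length does not match column count")
  if (any(!nzchar(drug_ids)) || anyNA(drug_ids))
    stop("drug_ids must be non-empty strings")
  dup <- drug_ids[duplicated(drug_ids)]
  if (length(dup))
    stop("duplicate drug_id: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(descriptor_names))
    stop("duplicate descriptor names: ",
         paste(unique(descriptor_names[duplicated(descriptor_names)]), collapse = ", "))
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stop("missing_mask shape mismatch")
  dimnames(values) <- list(drug_ids, descriptor_names)
  dimnames(missing_mask) <- dimnames(values)
  structure(list(drug_ids = drug_ids, descriptor_names = descriptor_names,
                 values = values, missing_mask = missing_mask),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("descriptor_matrix: %d drugs x %d descriptors (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' Read a drug-by-descriptor table
#'
#' First column must be `drug_id`, remaining columns numeric descriptors.
#' Empty or non-numeric cells are flagged in the missing mask and stored as
#' `NA`. A column with no parseable value at all is retained (the cleaning
#' stage drops it) but triggers a warning.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param delimiter field separator; default chosen from the file extension.
#' @return A [descriptor_matrix()].
#' @export
read_descriptor_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path, delimiter)
  raw <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("descriptor table needs a drug_id column plus descriptors")
  ids <- raw[[1]]
  chr <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(chr), nrow = nrow(chr),
                                 dimnames = dimnames(chr)))
  mask <- is.na(num)
  dead <- colSums(!mask) == 0
  if (any(dead))
    warning("fully non-numeric descriptor column(s): ",
            paste(colnames(chr)[dead], collapse = ", "),
            " (retained for the cleaning stage)")
  descriptor_matrix(num, drug_ids = ids, descriptor_names = colnames(chr),
                    missing_mask = mask)
}

#' Write a descriptor matrix
#'
#' Masked cells are written as empty fields so a round trip reproduces the
#' mask.
#'
#' @param D a [descriptor_matrix()].
#' @param path output path.
#' @param delimiter field separator; default chosen from the file extension.
#' @export
write_descriptor_table <- function(D, path, delimiter = NULL) {
  stopifnot(inherits(D, "descriptor_matrix"))
  delim <- detect_delim(path, delimiter)
  vals <- D$values
  vals[D$missing_mask] <- NA
  df <- data.frame(drug_id = D$drug_ids, vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a fingerprint set
#'
#' @param bits integer 0/1 matrix, drugs by bits.
#' @param drug_ids row identifiers.
#' @param kind free-text label for the fingerprint family (e.g.
#'   `"pubchem-like"`). The package treats all binary fingerprints uniformly;
#'   the label is metadata.
#' @return Object of class `fingerprint_set` with fields `drug_ids`,
#'   `n_bits`, `bits`, `kind`.
#' @export
fingerprint_set <- function(bits, drug_ids = rownames(bits), kind = "unknown") {
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0, 1)))
    stop("fingerprint bits must be 0 or 1")
  storage.mode(bits) <- "integer"
  drug_ids <- as.character(drug_ids)
  if (length(drug_ids) != nrow(bits)) stop("drug_ids length mismatch")
  if (anyDuplicated(drug_ids)) stop("duplicate drug_id in fingerprint set")
  rownames(bits) <- drug_ids
  structure(list(drug_ids = drug_ids, n_bits = ncol(bits), bits = bits,
                 kind = kind), class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("fingerprint_set (%s): %d drugs x %d bits\n",
              x$kind, length(x$drug_ids), x$n_bits))
  invisible(x)
}

#' Read a binary fingerprint table
#'
#' First column `drug_id`, remaining columns bits. Any cell outside `{0,1}`
#' is an error reported with its coordinates. All-zero rows are accepted;
#' their Tanimoto handling is defined by [tanimoto()].
#'
#' @inheritParams read_descriptor_table
#' @param kind label stored on the returned set.
#' @return A [fingerprint_set()].
#' @export
read_fingerprints <- function(path, delimiter = NULL, kind = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path, delimiter)
  raw <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           stringsAsFactors = FALSE)
  ids <- raw[[1]]
  chr <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(matrix(!(chr %in% c("0", "1")), nrow = nrow(chr)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("fingerprint cell not 0/1 at drug '%s', bit column '%s' (value '%s')",
                 ids[bad[1, 1]], colnames(chr)[bad[1, 2]], chr[bad[1, , drop = FALSE]]))
  }
  bits <- matrix(as.integer(chr), nrow = nrow(chr), dimnames = list(ids, colnames(chr)))
  fingerprint_set(bits, drug_ids = ids, kind = kind)
}

#' Write a fingerprint set
#'
#' @param fps a [fingerprint_set()].
#' @inheritParams write_descriptor_table
#' @export
write_fingerprints <- function(fps, path, delimiter = NULL) {
  stopifnot(inherits(fps, "fingerprint_set"))
  delim <- detect_delim(path, delimiter)
  df <- data.frame(drug_id = fps$drug_ids, fps$bits, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a drug-target interaction map
#'
#' Stores the bipartite drug-target graph with both orientations so degree
#' sums and reverse lookups stay consistent.
#'
#' @param drug_to_targets named list: `drug_id` -> character vector of
#'   target ids (non-empty, deduplicated).
#' @return Object of class `interaction_map` with `drug_to_targets`,
#'   `target_to_drugs` and `n_interactions`.
#' @export
interaction_map <- function(drug_to_targets) {
  if (length(drug_to_targets) == 0) {
    return(structure(list(drug_to_targets = list(), target_to_drugs = list(),
                          n_interactions = 0L), class = "interaction_map"))
  }
  if (is.null(names(drug_to_targets)) || any(!nzchar(names(drug_to_targets))))
    stop("drug_to_targets must be a named list")
  drug_to_targets <- lapply(drug_to_targets, function(x) sort(unique(as.character(x))))
  if (any(lengths(drug_to_targets) == 0))
    stop("every drug present must map to at least one target")
  edges <- data.frame(
    drug = rep(names(drug_to_targets), lengths(drug_to_targets)),
    target = unlist(drug_to_targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  target_to_drugs <- split(edges$drug, edges$target)
  target_to_drugs <- lapply(target_to_drugs, function(x) sort(unique(x)))
  structure(list(drug_to_targets = drug_to_targets,
                 target_to_drugs = target_to_drugs,
                 n_interactions = nrow(edges)),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("interaction_map: %d drugs, %d targets, %d interactions\n",
              length(x$drug_to_targets), length(x$target_to_drugs),
              x$n_interactions))
  invisible(x)
}

#' Targets annotated for a drug
#' @param map an [interaction_map()].
#' @param drug_id drug identifier.
#' @return Character vector of target ids (empty if the drug is absent).
#' @export
drug_targets <- function(map, drug_id) {
  stopifnot(inherits(map, "interaction_map"))
  map$drug_to_targets[[drug_id]] %||% character(0)
}

#' Drugs annotated as binding a target
#' @inheritParams drug_targets
#' @param target_id target identifier.
#' @export
target_drugs <- function(map, target_id) {
  stopifnot(inherits(map, "interaction_map"))
  map$target_to_drugs[[target_id]] %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a drug-target interaction table
#'
#' Two-column TSV/CSV `(drug_id, target_id)`; a header row is recognised by
#' its column names and skipped. Duplicate rows collapse to one interaction.
#'
#' @inheritParams read_descriptor_table
#' @return An [interaction_map()].
#' @export
read_interactions <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path, delimiter)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) {
    warning("empty interaction file: ", path)
    return(interaction_map(list()))
  }
  fields <- strsplit(lines[lines_keep], delim, fixed = TRUE)
  first <- tolower(trimws(fields[[1]]))
  if (length(first) >= 2 && first[1] %in% c("drug_id", "drug") &&
      first[2] %in% c("target_id", "target")) {
    fields <- fields[-1]
    lines_keep <- lines_keep[-1]
  }
  if (length(fields) == 0) {
    warning("interaction file has a header but no rows: ", path)
    return(interaction_map(list()))
  }
  ok <- vapply(fields, function(f) length(f) >= 2 && all(nzchar(trimws(f[1:2]))),
               logical(1))
  if (any(!ok))
    stop("interaction row with missing field at line ",
         lines_keep[which(!ok)[1]], " of ", path)
  edges <- unique(data.frame(
    drug = vapply(fields, function(f) trimws(f[1]), character(1)),
    target = vapply(fields, function(f) trimws(f[2]), character(1)),
    stringsAsFactors = FALSE))
  map <- interaction_map(split(edges$target, edges$drug))
  message(sprintf("read %d drugs, %d targets, %d interactions from %s",
                  length(map$drug_to_targets), length(map$target_to_drugs),
                  map$n_interactions, path))
  map
}

#' Write an interaction map
#' @param map an [interaction_map()].
#' @inheritParams write_descriptor_table
#' @export
write_interactions <- function(map, path, delimiter = NULL) {
  stopifnot(inherits(map, "interaction_map"))
  delim <- detect_delim(path, delimiter)
  df <- data.frame(
    drug_id = rep(names(map$drug_to_targets), lengths(map$drug_to_targets)),
    target_id = unlist(map$drug_to_targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ATC codes are 7 characters (letter, 2 digits, letter, letter, 2 digits);
# any prefix cut at a level boundary (1, 3, 4, 5 or 7 chars) is also valid.
is_valid_atc <- function(code) {
  grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", code) &
    nchar(code) %in% c(1L, 3L, 4L, 5L, 7L)
}

#' Construct an annotation map
#'
#' Maps entity ids (targets for `kind = "domain"`, drugs for `kind = "atc"`)
#' to sets of annotation strings. ATC codes are validated against the WHO
#' 7-character grammar (letter, two digits, letter, letter, two digits) or a
#' level-boundary prefix of it.
#'
#' @param mapping named list: entity id -> character vector of annotations.
#' @param kind `"domain"` or `"atc"`.
#' @return Object of class `annotation_map`.
#' @export
annotation_map <- function(mapping, kind = c("domain", "atc")) {
  kind <- match.arg(kind)
  if (length(mapping) > 0 &&
      (is.null(names(mapping)) || any(!nzchar(names(mapping)))))
    stop("mapping must be a named list")
  mapping <- lapply(mapping, function(x) sort(unique(as.character(x))))
  if (kind == "atc") {
    codes <- unlist(mapping, use.names = FALSE)
    bad <- codes[!is_valid_atc(codes)]
    if (length(bad))
      stop("invalid ATC code(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(kind = kind, mapping = mapping), class = "annotation_map")
}

#' Read an annotation table
#'
#' Two-column TSV/CSV `(entity_id, annotation)`, optional header.
#'
#' @inheritParams read_descriptor_table
#' @param kind `"domain"` or `"atc"` (ATC codes are grammar-checked at load).
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, kind = c("domain", "atc"), delimiter = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path, delimiter)
  raw <- utils::read.table(path, sep = delim, header = FALSE, comment.char = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("annotation table needs two columns")
  first <- tolower(trimws(unlist(raw[1, 1:2])))
  if (any(first %in% c("entity_id", "drug_id", "target_id")))
    raw <- raw[-1, , drop = FALSE]
  annotation_map(split(trimws(raw[[2]]), trimws(raw[[1]])), kind = kind)
}

#' Write an annotation map
#' @param amap an [annotation_map()].
#' @inheritParams write_descriptor_table
#' @export
write_annotations <- function(amap, path, delimiter = NULL) {
  stopifnot(inherits(amap, "annotation_map"))
  delim <- detect_delim(path, delimiter)
  df <- data.frame(
    entity_id = rep(names(amap$mapping), lengths(amap$mapping)),
    annotation = unlist(amap$mapping, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Compute binary fingerprints from SMILES
#'
#' Convenience path when no precomputed fingerprint table is available:
#' atom-pair fingerprints folded to 1024 bits via the ChemmineR toolkit.
#' Records whose SMILES cannot be parsed are skipped with a message listing
#' their ids. Deterministic: the same SMILES always yields the same row.
#'
#' @param records data.frame with columns `drug_id` and `smiles`.
#' @param kind label stored on the result.
#' @return A [fingerprint_set()] over the parseable records.
#' @export
compute_fingerprints <- function(records, kind = "atompair-1024") {
  stopifnot(is.data.frame(records), all(c("drug_id", "smiles") %in% names(records)))
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("the ChemmineR toolkit is not installed; supply a precomputed ",
         "fingerprint table via read_fingerprints() instead")
  if (anyNA(records$smiles) || any(!nzchar(records$smiles)))
    stop("every record needs a SMILES string")
  # reference atom-pair vocabulary for the 1024-bit folding
  ref <- new.env(parent = emptyenv())
  utils::data("apfp", package = "ChemmineR", envir = ref)
  descnames <- as.character(ref$apfp$AP)[1:1024]
  rows <- vector("list", nrow(records))
  failed <- character(0)
  for (i in seq_len(nrow(records))) {
    fp <- tryCatch({
      smi <- stats::setNames(records$smiles[i], records$drug_id[i])
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
      ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
      as.integer(ChemmineR::desc2fp(ap, descnames = descnames,
                                    type = "matrix")[1, ])
    }, error = function(e) NULL)
    if (is.null(fp)) failed <- c(failed, records$drug_id[i])
    else rows[[i]] <- fp
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (length(failed))
    message("skipped unparsable SMILES for: ", paste(failed, collapse = ", "))
  if (!any(keep)) stop("no SMILES could be parsed")
  bits <- do.call(rbind, rows[keep])
  fingerprint_set(bits, drug_ids = records$drug_id[keep], kind = kind)
}
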