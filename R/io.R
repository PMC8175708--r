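# Readers and writers for the plain-text interchange formats.
#
# All CSVs are comma-separated UTF-8 with a required header row; column names
# are matched case-insensitively. TSVs are used for kernels, fingerprints and
# kinase annotations.

read_csv_ci <- function(path, required, col_types) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(tbl) <- tolower(names(tbl))
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s) %s.", path, paste(missing_cols, collapse = ", ")))
  }
  tbl
}

#' Read and write bioactivity tables
#'
#' The bioactivity CSV is the long-format exchange for raw assay records:
#' columns `compound_id`, `protein_id`, `assay_type`, `value`, `unit`.
#'
#' @param path File path.
#' @return `read_bioactivity()` returns a tibble of bioactivity records.
#' @export
read_bioactivity <- function(path) {
  tbl <- read_csv_ci(path, c("compound_id", "protein_id", "assay_type", "value", "unit"))
  value <- suppressWarnings(as.numeric(tbl$value))
  if (anyNA(value)) {
    bad <- which(is.na(value))[1]
    abort(sprintf("%s: non-numeric value %s at data row %d.", path, tbl$value[bad], bad))
  }
  bad_type <- setdiff(unique(tbl$assay_type), assay_types)
  if (length(bad_type) > 0) {
    abort(sprintf("%s: unknown assay type(s) %s.", path, paste(bad_type, collapse = ", ")))
  }
  tibble(
    compound_id = tbl$compound_id,
    protein_id = tbl$protein_id,
    assay_type = tbl$assay_type,
    value = value,
    unit = tbl$unit
  )
}

#' @rdname read_bioactivity
#' @param records Bioactivity tibble to serialise.
#' @export
write_bioactivity <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read and write prediction files
#'
#' A prediction file holds one predicted pKd per compound-kinase pair:
#' columns `compound_id`, `protein_id`, `pkd_pred`. Values are written at full
#' precision so a write/read round trip is bit-identical.
#'
#' @param path File path.
#' @param model_id Optional model identifier attached to the returned tibble
#'   as the `"model_id"` attribute.
#' @return A prediction tibble (`compound_id`, `protein_id`, `pkd_pred`).
#' @export
read_predictions <- function(path, model_id = basename(path)) {
  tbl <- read_csv_ci(path, c("compound_id", "protein_id", "pkd_pred"))
  value <- suppressWarnings(as.numeric(tbl$pkd_pred))
  if (anyNA(value)) {
    bad <- which(is.na(value))[1]
    abort(sprintf("%s: non-numeric pkd_pred at data row %d.", path, bad))
  }
  out <- tibble(compound_id = tbl$compound_id, protein_id = tbl$protein_id, pkd_pred = value)
  attr(out, "model_id") <- model_id
  out
}

#' @rdname read_predictions
#' @param pred Prediction tibble to serialise.
#' @export
write_predictions <- function(pred, path) {
  assert_predictions(pred)
  out <- pred
  # serialize at full double precision (17 significant digits round-trips)
  out$pkd_pred <- sprintf("%.17g", pred$pkd_pred)
  readr::write_csv(out, path)
  invisible(path)
}

#' Validate a submitted prediction file against a pair template
#'
#' Blinded-evaluation submissions must cover exactly the declared template of
#' compound-kinase pairs with numeric pKd predictions. On success the parsed
#' prediction set is returned; on any violation a validation report (class
#' `"kb_validation"`) is returned listing every problem found: missing pairs,
#' extra pairs, duplicated pairs and non-numeric values.
#'
#' @param path Path to the prediction CSV
#'   (columns `compound_id`, `protein_id`, `pkd_pred`).
#' @param template A data frame with columns `compound_id`, `protein_id`
#'   defining the exact pair set the file must cover.
#' @return A prediction tibble if valid, otherwise a `kb_validation` object
#'   whose `$violations` tibble has columns `type`, `compound_id`,
#'   `protein_id`, `detail`.
#' @export
validate_prediction_file <- function(path, template) {
  if (!file.exists(path)) {
    abort(sprintf("Prediction file not found: %s.", path))
  }
  tbl <- tryCatch(
    read_csv_ci(path, c("compound_id", "protein_id", "pkd_pred")),
    error = function(e) e
  )
  if (inherits(tbl, "error")) {
    abort(sprintf("Could not parse %s: %s", path, conditionMessage(tbl)))
  }
  viol <- list()
  value <- suppressWarnings(as.numeric(tbl$pkd_pred))
  bad <- is.na(value) | !is.finite(value)
  if (any(bad)) {
    viol$non_numeric <- tibble(
      type = "non_numeric",
      compound_id = tbl$compound_id[bad],
      protein_id = tbl$protein_id[bad],
      detail = sprintf("value '%s' at data row %d", tbl$pkd_pred[bad], which(bad))
    )
  }
  keys <- pair_key(tbl$compound_id, tbl$protein_id)
  dup <- duplicated(keys)
  if (any(dup)) {
    viol$duplicate <- tibble(
      type = "duplicate",
      compound_id = tbl$compound_id[dup],
      protein_id = tbl$protein_id[dup],
      detail = sprintf("pair repeated at data row %d", which(dup))
    )
  }
  tmpl_keys <- pair_key(template$compound_id, template$protein_id)
  missing_idx <- which(!tmpl_keys %in% keys)
  if (length(missing_idx) > 0) {
    viol$missing <- tibble(
      type = "missing_pair",
      compound_id = template$compound_id[missing_idx],
      protein_id = template$protein_id[missing_idx],
      detail = "template pair absent from file"
    )
  }
  extra_idx <- which(!keys %in% tmpl_keys)
  if (length(extra_idx) > 0) {
    viol$extra <- tibble(
      type = "extra_pair",
      compound_id = tbl$compound_id[extra_idx],
      protein_id = tbl$protein_id[extra_idx],
      detail = "pair not in template"
    )
  }
  if (length(viol) > 0) {
    report <- structure(
      list(path = path, valid = FALSE, violations = list_rbind(unname(viol))),
      class = "kb_validation"
    )
    return(report)
  }
  out <- tibble(compound_id = tbl$compound_id, protein_id = tbl$protein_id, pkd_pred = value)
  # return rows in template order
  out <- out[match(tmpl_keys, keys), , drop = FALSE]
  attr(out, "model_id") <- basename(path)
  out
}

#' @export
print.kb_validation <- function(x, ...) {
  cat(sprintf("Invalid prediction file: %s\n%d violation(s):\n", x$path, nrow(x$violations)))
  print(x$violations, ...)
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' The protein id is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `protein_id`, `sequence`.
#' @export
read_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  tibble(protein_id = ids, sequence = unname(as.character(seqs)))
}

#' @rdname read_proteins
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @export
write_proteins <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$protein_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read compound structures from a .smi file
#'
#' One `SMILES<TAB>compound_id` record per line.
#'
#' @param path .smi file path.
#' @return A tibble with columns `compound_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d is not 'SMILES<TAB>compound_id'.", path, bad[1]))
  }
  tibble(
    compound_id = map_chr(parts, 2),
    smiles = map_chr(parts, 1)
  )
}

#' Read and write kinase annotations
#'
#' Annotation TSVs map each kinase to its group (e.g. CMGC, TK) and family,
#' one row per protein id.
#'
#' @param path Annotation TSV path (columns `protein_id`, `group`, `family`).
#' @return A tibble with one annotation row per protein.
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  missing_cols <- setdiff(c("protein_id", "group", "family"), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tbl$protein_id)) {
    abort(sprintf("%s: duplicated protein_id rows.", path))
  }
  as_tibble(tbl[, c("protein_id", "group", "family")])
}

#' @rdname read_annotations
#' @param annotations Tibble with `protein_id`, `group`, `family`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Count the pair/compound/kinase composition of a challenge test set
#'
#' Summarises an interaction table (optionally split by a `round` column) into
#' the counts used to describe blinded test datasets: number of pairs, distinct
#' compounds and distinct kinases, plus the union across rounds.
#'
#' @param interactions Interaction table, optionally with a `round` column.
#' @return A tibble with one row per round plus a `"union"` row, columns
#'   `round`, `n_pairs`, `n_compounds`, `n_kinases`.
#' @export
challenge_counts <- function(interactions) {
  assert_interactions(interactions)
  if (!"round" %in% names(interactions)) {
    interactions$round <- "all"
  }
  per_round <- interactions |>
    summarise(
      n_pairs = n(),
      n_compounds = n_distinct(.data$compound_id),
      n_kinases = n_distinct(.data$protein_id),
      .by = "round"
    )
  union_row <- tibble(
    round = "union",
    n_pairs = nrow(interactions),
    n_compounds = n_distinct(interactions$compound_id),
    n_kinases = n_distinct(interactions$protein_id)
  )
  bind_rows(per_round, union_row)
}
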