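#' Assay types and units recognised in bioactivity tables
#'
#' Concentration-type assays (Kd, Ki, IC50, EC50) carry molar-family units and
#' can be converted to the pKd scale; percentage-type assays (single-dose
#' inhibition, activity) carry the unit `"PCT"` and pass through untransformed.
#'
#' @format Character vectors of the recognised codes.
#' @name assay_vocabulary
NULL

#' @rdname assay_vocabulary
#' @export
assay_types <- c("KD", "KI", "IC50", "EC50", "INHIBITION_PCT", "ACTIVITY_PCT")

#' @rdname assay_vocabulary
#' @export
concentration_assays <- c("KD", "KI", "IC50", "EC50")

.molar_factor <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Convert a measured concentration to the pKd scale
#'
#' The modelling and scoring scale throughout is pKd = -log10(Kd in molar).
#' A 10 nM Kd therefore becomes pKd 8, and the 10 uM assay ceiling becomes
#' pKd 5. Conversion is exact for powers of ten.
#'
#' @param value Measured value(s), non-negative.
#' @param unit Unit code(s), one of `"M"`, `"mM"`, `"uM"`, `"nM"`.
#' @param assay_type Assay type code(s); must be concentration assays
#'   (`"KD"`, `"KI"`, `"IC50"`, `"EC50"`). Percentage assays cannot be put on
#'   the pKd scale and raise an error.
#' @return Numeric vector of pKd values.
#' @examples
#' to_pkd(10, "nM")    # 8
#' to_pkd(10, "uM")    # 5, the single-dose assay ceiling
#' @export
to_pkd <- function(value, unit, assay_type = "KD") {
  n <- max(length(value), length(unit), length(assay_type))
  value <- rep_len(value, n)
  unit <- rep_len(unit, n)
  assay_type <- rep_len(assay_type, n)
  bad_type <- !assay_type %in% concentration_assays
  if (any(bad_type)) {
    abort(sprintf(
      "Percentage-type assays cannot be converted to pKd (got %s).",
      paste(unique(assay_type[bad_type]), collapse = ", ")
    ))
  }
  bad_unit <- !unit %in% names(.molar_factor)
  if (any(bad_unit)) {
    abort(sprintf(
      "Unknown molar unit(s): %s. Use one of %s.",
      paste(unique(unit[bad_unit]), collapse = ", "),
      paste(names(.molar_factor), collapse = ", ")
    ))
  }
  if (anyNA(value) || any(!is.finite(value)) || any(value < 0)) {
    abort("Bioactivity values must be finite and non-negative.")
  }
  if (any(value == 0)) {
    abort("A measured concentration of 0 has no pKd (log of zero).")
  }
  # exact for powers of ten: split the unit exponent out of the log
  unname(-(log10(value) + log10(.molar_factor[unit])))
}

#' Merge replicate bioactivity measurements into an interaction table
#'
#' Replicate measurements of the same compound-kinase pair are merged by taking
#' the median of their pKd-converted values (merging happens on the modelling
#' scale, not on raw Kd). Records whose assay type is outside `assay_filter`
#' are dropped before conversion.
#'
#' @param records A data frame of bioactivity records with columns
#'   `compound_id`, `protein_id`, `assay_type`, `value`, `unit`.
#' @param assay_filter Character vector of assay types to retain
#'   (default `"KD"` only, the dose-response binding assays).
#' @return An interaction table: a tibble with one row per retained
#'   (compound, protein) pair and columns `compound_id`, `protein_id`, `pkd`.
#'   Empty input (after filtering) yields an empty table, not an error.
#' @examples
#' recs <- tibble::tibble(
#'   compound_id = "c1", protein_id = "p1", assay_type = "KD",
#'   value = c(10, 100, 1), unit = "nM"
#' )
#' merge_replicates(recs) # median of pKd {8, 7, 9} -> 8
#' @export
merge_replicates <- function(records, assay_filter = "KD") {
  missing_cols <- setdiff(
    c("compound_id", "protein_id", "assay_type", "value", "unit"),
    names(records)
  )
  if (length(missing_cols) > 0) {
    abort(sprintf("`records` is missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  kept <- filter(records, .data$assay_type %in% assay_filter)
  if (nrow(kept) == 0) {
    return(tibble(compound_id = character(), protein_id = character(), pkd = double()))
  }
  kept |>
    mutate(pkd = to_pkd(.data$value, .data$unit, .data$assay_type)) |>
    summarise(
      pkd = median(.data$pkd),
      .by = c("compound_id", "protein_id")
    ) |>
    arrange(.data$compound_id, .data$protein_id)
}

#' Training-data drop-out filters
#'
#' Drop-out experiments probe how a model's accuracy depends on the training
#' data: `filter_by_similarity()` removes every training compound whose maximum
#' Tanimoto similarity to any test compound reaches `threshold` (closed bound:
#' ties at the threshold are removed), `filter_by_pkd_range()` keeps only rows
#' with `lo <= pkd <= hi`, and `random_dropout()` removes a fixed number of
#' uniformly sampled rows, reproducibly for a given seed.
#'
#' @param train Interaction table of training rows
#'   (`compound_id`, `protein_id`, `pkd`).
#' @param train_fps,test_fps Fingerprint matrices (rows = compounds, rownames =
#'   compound ids) as built by [fingerprint_matrix()]; every training compound
#'   must be present in `train_fps`.
#' @param threshold Tanimoto similarity threshold in \[0, 1\]. Lower thresholds
#'   never retain more rows (at 0 everything is removed).
#' @return A filtered interaction table.
#' @seealso [similarity_kernel()] for the Tanimoto computation.
#' @export
filter_by_similarity <- function(train, train_fps, test_fps, threshold) {
  assert_interactions(train, "train")
  check_scalar_number(threshold, "threshold", 0, 1)
  train_cmpds <- unique(train$compound_id)
  missing_fp <- setdiff(train_cmpds, rownames(train_fps))
  if (length(missing_fp) > 0) {
    abort(sprintf("No fingerprint for training compound(s): %s.", paste(missing_fp, collapse = ", ")))
  }
  cross <- cross_similarity(train_fps[train_cmpds, , drop = FALSE], test_fps, metric = "tanimoto")
  max_sim <- apply(cross, 1, max)
  removed <- train_cmpds[max_sim >= threshold]
  filter(train, !.data$compound_id %in% removed)
}

#' @rdname filter_by_similarity
#' @param lo,hi Inclusive pKd bounds; `lo <= hi` required.
#' @export
filter_by_pkd_range <- function(train, lo = -Inf, hi = Inf) {
  assert_interactions(train, "train")
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 || length(hi) != 1 || lo > hi) {
    abort("`lo` and `hi` must be single numbers with lo <= hi.")
  }
  filter(train, .data$pkd >= lo, .data$pkd <= hi)
}

#' @rdname filter_by_similarity
#' @param n_remove Number of rows to remove, at most `nrow(train)`.
#' @param seed Integer seed; the same seed reproduces the same removal.
#' @export
random_dropout <- function(train, n_remove, seed) {
  assert_interactions(train, "train")
  if (!is.numeric(n_remove) || length(n_remove) != 1 || n_remove < 0 || n_remove != round(n_remove)) {
    abort("`n_remove` must be a single non-negative integer.")
  }
  if (n_remove > nrow(train)) {
    abort(sprintf("Cannot remove %d rows from a table of %d.", n_remove, nrow(train)))
  }
  if (n_remove == 0) {
    return(train)
  }
  drop_idx <- withr::with_seed(seed, sample.int(nrow(train), n_remove))
  train[-drop_idx, , drop = FALSE]
}
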