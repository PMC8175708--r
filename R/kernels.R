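#' Kernel matrices over compounds or proteins
#'
#' A `kb_kernel` is a symmetric similarity matrix with entity ids on both
#' dimensions; it is the input to all KronRLS regressors. Similarity kernels
#' are normalised so the diagonal is exactly 1 and entries lie in \[0, 1\].
#'
#' @param values Symmetric numeric matrix.
#' @param ids Entity identifiers, one per row/column (defaults to rownames).
#' @return An object of class `"kb_kernel"` with elements `ids` and `values`.
#' @export
kernel_matrix <- function(values, ids = rownames(values)) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("A kernel must be a square matrix.")
  }
  if (is.null(ids)) abort("Kernel entities need ids (rownames or `ids`).")
  ids <- as.character(ids)
  if (length(ids) != nrow(values) || anyDuplicated(ids)) {
    abort("`ids` must be unique, one per kernel row.")
  }
  if (max(abs(values - t(values))) > 1e-10) {
    abort("Kernel matrix is not symmetric (tolerance 1e-10).")
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values), class = "kb_kernel")
}

#' @export
print.kb_kernel <- function(x, ...) {
  cat(sprintf("<kb_kernel> %d entities: %s%s\n", length(x$ids),
              paste(head(x$ids, 4), collapse = ", "),
              if (length(x$ids) > 4) ", ..." else ""))
  invisible(x)
}

#' @export
dim.kb_kernel <- function(x) dim(x$values)

#' @rdname kernel_matrix
#' @param x Object to test or convert.
#' @export
is_kernel <- function(x) inherits(x, "kb_kernel")

kernel_values <- function(kernel, ids = NULL) {
  if (!is_kernel(kernel)) abort("Expected a `kb_kernel` object.")
  if (is.null(ids)) return(kernel$values)
  missing_ids <- setdiff(ids, kernel$ids)
  if (length(missing_ids) > 0) {
    abort(sprintf("Entity id(s) absent from kernel: %s.", paste(missing_ids, collapse = ", ")))
  }
  kernel$values[ids, ids, drop = FALSE]
}

# Pairwise similarity between the rows of two fingerprint matrices.
cross_similarity <- function(a, b, metric = c("tanimoto", "dice")) {
  metric <- match.arg(metric)
  if (ncol(a) != ncol(b)) abort("Fingerprints have mismatched bit lengths.")
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  inter <- a %*% t(b)
  pa <- rowSums(a)
  pb <- rowSums(b)
  if (metric == "tanimoto") {
    denom <- outer(pa, pb, `+`) - inter
  } else {
    inter <- 2 * inter
    denom <- outer(pa, pb, `+`)
  }
  ifelse(denom > 0, inter / denom, 0)
}

#' Fingerprint similarity kernel (Tanimoto or Dice)
#'
#' Builds the compound kernel from bit fingerprints:
#' Tanimoto(a, b) = |a AND b| / |a OR b| and
#' Dice(a, b) = 2 |a AND b| / (|a| + |b|). The diagonal is set to 1
#' (including for all-zero fingerprints, whose off-diagonal similarity is 0).
#' Dice dominates Tanimoto entrywise.
#'
#' @param fps 0/1 fingerprint matrix (rows = compounds, rownames = ids), e.g.
#'   from [fingerprint_matrix()].
#' @param metric `"tanimoto"` (default) or `"dice"`.
#' @return A [kernel_matrix()] over the compounds.
#' @export
similarity_kernel <- function(fps, metric = c("tanimoto", "dice")) {
  metric <- match.arg(metric)
  if (is.null(rownames(fps))) abort("Fingerprint matrix needs compound ids as rownames.")
  sim <- cross_similarity(fps, fps, metric)
  diag(sim) <- 1
  kernel_matrix(sim, rownames(fps))
}

#' Alignment scoring scheme for protein kernels
#'
#' Smith-Waterman local alignment under affine gaps: a gap of length L costs
#' `gap_open + L * gap_extend`. The default scheme is BLOSUM62 with gap open
#' 11 and extend 1, the ubiquitous protein-alignment defaults.
#'
#' @param substitution_matrix A named Biostrings substitution matrix
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or a numeric matrix.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An object of class `"aln_scoring"`.
#' @export
alignment_scoring <- function(substitution_matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  if (gap_open < 0 || gap_extend < 0) abort("Gap penalties must be non-negative.")
  if (is.character(substitution_matrix)) {
    name <- substitution_matrix
    env <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = env)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(name, envir = env)) {
      abort(sprintf("Unknown substitution matrix '%s'.", name))
    }
    substitution_matrix <- get(name, envir = env)
  } else {
    name <- "custom"
  }
  structure(
    list(substitution_matrix = substitution_matrix, name = name,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "aln_scoring"
  )
}

.aa_alphabet_regex <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

check_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    abort(sprintf("%s must be a non-empty string.", what))
  }
  if (!grepl(.aa_alphabet_regex, seq)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seq)
    abort(sprintf("Illegal residue '%s' at position %d of %s.",
                  substr(seq, bad, bad), bad, what))
  }
  invisible(seq)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local-alignment score under affine gap penalties. The score is
#' non-negative (the empty alignment scores 0) and symmetric in its arguments.
#' Sequences are over the 20-letter amino-acid alphabet plus X.
#'
#' @param a,b Amino-acid sequences as strings.
#' @param scoring An [alignment_scoring()] scheme.
#' @return Single numeric alignment score.
#' @export
sw_score <- function(a, b, scoring = alignment_scoring()) {
  check_sequence(a, "sequence `a`")
  check_sequence(b, "sequence `b`")
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE
  )
  max(0, s)
}

#' Normalized Smith-Waterman protein kernel
#'
#' The protein kernel entry for sequences i and j is
#' sw(i, j) / sqrt(sw(i, i) * sw(j, j)), so the diagonal is exactly 1 and all
#' entries lie in \[0, 1\]. A sequence whose self-alignment score is zero
#' (degenerate, e.g. all-X) cannot be normalised and raises an error.
#'
#' @param proteins A data frame with columns `protein_id`, `sequence`.
#' @param scoring An [alignment_scoring()] scheme.
#' @return A [kernel_matrix()] over the proteins.
#' @export
protein_kernel <- function(proteins, scoring = alignment_scoring()) {
  ids <- proteins$protein_id
  seqs <- proteins$sequence
  if (anyDuplicated(ids)) abort("Protein ids must be unique.")
  for (i in seq_along(seqs)) check_sequence(seqs[i], paste0("sequence ", ids[i]))
  n <- length(seqs)
  aaset <- Biostrings::AAStringSet(seqs)
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      aaset[i:n], aaset[[i]], type = "local",
      substitutionMatrix = scoring$substitution_matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = TRUE
    )
    raw[i, i:n] <- raw[i:n, i] <- pmax(0, sc)
  }
  self <- diag(raw)
  if (any(self <= 0)) {
    abort(sprintf("Degenerate sequence(s) with zero self-alignment score: %s.",
                  paste(ids[self <= 0], collapse = ", ")))
  }
  norm <- raw / sqrt(outer(self, self))
  diag(norm) <- 1
  kernel_matrix(pmin(norm, 1), ids)
}

#' Repair a kernel to positive semidefiniteness
#'
#' Normalised alignment kernels need not be PSD. If the smallest eigenvalue
#' is negative, `(|lambda_min| + eps)` is added to the diagonal and the matrix
#' rescaled back to unit diagonal — a diagonal shift preserves the ordering of
#' off-diagonal similarities (unlike eigenvalue clipping). Already-PSD kernels
#' are returned unchanged.
#'
#' @param kernel A [kernel_matrix()].
#' @param eps Extra non-negative shift beyond `|lambda_min|` (default 1e-8).
#' @return A PSD [kernel_matrix()] with unit diagonal.
#' @export
ensure_psd <- function(kernel, eps = 1e-8) {
  if (!is_kernel(kernel)) abort("Expected a `kb_kernel` object.")
  if (eps < 0) abort("`eps` must be non-negative.")
  vals <- kernel$values
  lam_min <- min(eigen(vals, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min >= 0) return(kernel)
  shift <- abs(lam_min) + eps
  vals <- vals + diag(shift, nrow(vals))
  d <- diag(vals)
  vals <- vals / sqrt(outer(d, d))
  diag(vals) <- 1
  kernel_matrix(vals, kernel$ids)
}

#' Serialise a kernel as TSV
#'
#' A leading id column, an id header row, values at 12 significant digits.
#'
#' @param kernel A [kernel_matrix()].
#' @param path Output TSV path.
#' @export
write_kernel <- function(kernel, path) {
  if (!is_kernel(kernel)) abort("Expected a `kb_kernel` object.")
  tbl <- as_tibble(signif(kernel$values, 12))
  tbl <- bind_cols(tibble(id = kernel$ids), tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tbl[[1]])
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  kernel_matrix(vals, ids)
}
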