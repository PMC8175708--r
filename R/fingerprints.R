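#' Fingerprint specifications
#'
#' A fingerprint spec fixes the hashing family used for compound bit vectors:
#' circular (Morgan/ECFP-style, `radius_or_depth` = radius) or path-based
#' (`radius_or_depth` = maximum path depth), folded to `n_bits` bits.
#' `n_bits` must be a positive power of two. The `use_chirality` flag is kept
#' as spec metadata for precomputed fingerprints; the OpenBabel hashing
#' backend does not encode chirality.
#'
#' @param kind `"circular"` or `"path"`.
#' @param radius_or_depth Circular radius (2 or 3 are conventional) or path
#'   depth; at least 1.
#' @param n_bits Fingerprint length (default 1024).
#' @param use_chirality Logical flag carried in the spec.
#' @return An object of class `"fp_spec"`.
#' @export
fingerprint_spec <- function(kind = c("circular", "path"), radius_or_depth = 2,
                             n_bits = 1024, use_chirality = FALSE) {
  kind <- match.arg(kind)
  if (radius_or_depth < 1) abort("`radius_or_depth` must be at least 1.")
  if (n_bits < 1 || bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) != 0L) {
    abort("`n_bits` must be a positive power of two.")
  }
  structure(
    list(kind = kind, radius_or_depth = as.integer(radius_or_depth),
         n_bits = as.integer(n_bits), use_chirality = isTRUE(use_chirality)),
    class = "fp_spec"
  )
}

#' @export
print.fp_spec <- function(x, ...) {
  cat(sprintf("<fp_spec> %s, radius/depth %d, %d bits, chirality %s\n",
              x$kind, x$radius_or_depth, x$n_bits, x$use_chirality))
  invisible(x)
}

# OR-fold a 0/1 matrix with native_bits columns down to n_bits columns.
fold_bits <- function(mat, n_bits) {
  if (ncol(mat) == n_bits) return(mat)
  if (ncol(mat) < n_bits) {
    abort(sprintf("Cannot expand a %d-bit fingerprint to %d bits.", ncol(mat), n_bits))
  }
  if (ncol(mat) %% n_bits != 0) {
    abort("Native fingerprint length is not a multiple of the requested n_bits.")
  }
  out <- matrix(0L, nrow(mat), n_bits, dimnames = list(rownames(mat), NULL))
  for (block in seq_len(ncol(mat) / n_bits)) {
    idx <- (block - 1L) * n_bits + seq_len(n_bits)
    out <- pmax(out, mat[, idx, drop = FALSE])
  }
  storage.mode(out) <- "integer"
  out
}

smiles_fingerprints <- function(smiles, ids, spec) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("Computing fingerprints from SMILES requires the ChemmineOB package.")
  }
  fp_name <- switch(spec$kind,
    path = "FP2",
    circular = paste0("ECFP", 2L * spec$radius_or_depth)
  )
  input <- paste0(smiles, "\t", ids, "\n", collapse = "")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(mols, fp_name),
    error = function(e) abort(sprintf("Fingerprint backend failed: %s", conditionMessage(e)))
  )
  raw <- matrix(as.integer(raw != 0), nrow = length(ids))
  if (nrow(raw) != length(ids)) {
    abort("Fingerprint backend returned an unexpected number of molecules (unparsable SMILES?).")
  }
  zero <- rowSums(raw) == 0
  if (any(zero)) {
    warn(sprintf("All-zero fingerprint for compound(s): %s.", paste(ids[zero], collapse = ", ")))
  }
  rownames(raw) <- ids
  fold_bits(raw, spec$n_bits)
}

#' Compute or validate compound fingerprints
#'
#' `fingerprint_matrix()` turns a compound table into a 0/1 matrix with one
#' row per compound (rownames = compound ids). Compounds may carry a
#' precomputed fingerprint (list-column `fingerprint` of 0/1 vectors of length
#' `spec$n_bits`, returned as-is after validation) or a `smiles` column from
#' which fingerprints are hashed deterministically via OpenBabel
#' (path kind: FP2; circular kind: ECFP at twice the radius), OR-folded to
#' `n_bits`.
#'
#' @param compounds A data frame with `compound_id` and at least one of
#'   `smiles` or `fingerprint`.
#' @param spec A [fingerprint_spec()].
#' @return Integer 0/1 matrix, `n_compounds x n_bits`, with the fp spec
#'   attached as attribute `"fp_spec"`.
#' @export
fingerprint_matrix <- function(compounds, spec = fingerprint_spec()) {
  if (!"compound_id" %in% names(compounds)) abort("`compounds` needs a compound_id column.")
  ids <- compounds$compound_id
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    abort("Compound ids must be non-empty and unique.")
  }
  has_fp <- "fingerprint" %in% names(compounds) &&
    !all(vapply(compounds$fingerprint, is.null, logical(1)))
  if (has_fp) {
    lens <- lengths(compounds$fingerprint)
    if (any(lens != spec$n_bits)) {
      abort(sprintf(
        "Precomputed fingerprint length mismatch for %s (expected %d bits).",
        paste(ids[lens != spec$n_bits], collapse = ", "), spec$n_bits
      ))
    }
    mat <- do.call(rbind, lapply(compounds$fingerprint, function(v) as.integer(v != 0)))
    rownames(mat) <- ids
  } else if ("smiles" %in% names(compounds)) {
    mat <- smiles_fingerprints(compounds$smiles, ids, spec)
  } else {
    abort("Each compound needs a precomputed `fingerprint` or a `smiles` structure.")
  }
  attr(mat, "fp_spec") <- spec
  mat
}

#' Serialise fingerprints as TSV of id + hex-encoded bitstring
#'
#' @param fps Fingerprint matrix from [fingerprint_matrix()].
#' @param path Output TSV path.
#' @export
write_fingerprints <- function(fps, path) {
  hex <- apply(fps, 1, function(bits) {
    nibbles <- matrix(bits, nrow = 4)
    paste(sprintf("%x", colSums(nibbles * c(8L, 4L, 2L, 1L))), collapse = "")
  })
  readr::write_tsv(tibble(compound_id = rownames(fps), bits = hex), path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @return `read_fingerprints()` returns the integer 0/1 matrix.
#' @export
read_fingerprints <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(tbl) <- tolower(names(tbl))
  if (!all(c("compound_id", "bits") %in% names(tbl))) {
    abort(sprintf("%s: expected columns compound_id, bits.", path))
  }
  mat <- do.call(rbind, lapply(tbl$bits, function(h) {
    vals <- strtoi(strsplit(h, "")[[1]], base = 16L)
    # each hex char expands to its 4 bits, most significant first
    as.integer(vapply(vals, function(v) bitwAnd(bitwShiftR(v, 3:0), 1L), integer(4)))
  }))
  rownames(mat) <- tbl$compound_id
  mat
}
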