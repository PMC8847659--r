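# TSV readers/writers for cohort tables, expression matrices, reference
# rankings and IC50 tables. All files are UTF-8 tab-separated with a header
# row and "NA" as the missing-value sentinel.

cohort_required_cols <- c(
  "patient_id", "cn_fzr1", "cn_usp10", "cn_usp13", "cn_skp2",
  "er", "pr", "her2", "p27", "os_time", "os_event",
  "stage", "grade", "positive_nodes"
)

#' Read a cohort table
#'
#' Reads and validates a per-patient TSV: unique patient ids, copy-number
#' levels restricted to \{-2..2\} (errors name the offending row and value),
#' non-negative survival times and node counts. `"NA"` cells become missing
#' values; rows with missing values are retained.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  # columns are read as character and converted with strtod-based as.numeric,
  # which (unlike the fast multi-threaded parser) is correctly rounded, so
  # write -> read -> write is bit-identical
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  num_cols <- intersect(c("p27", "os_time", "latent_skp2"), names(x))
  int_cols <- intersect(c("os_event", "positive_nodes"), names(x))
  for (cc in num_cols) x[[cc]] <- as.numeric(x[[cc]])
  for (cc in c(int_cols, intersect(c("cn_fzr1", "cn_usp10", "cn_usp13", "cn_skp2"),
                                   names(x)))) {
    x[[cc]] <- suppressWarnings(as.numeric(x[[cc]]))
  }
  missing_cols <- setdiff(cohort_required_cols, names(x))
  if (length(missing_cols)) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$patient_id)) {
    dup <- x$patient_id[duplicated(x$patient_id)][1]
    abort(sprintf("duplicate patient_id '%s'", dup))
  }
  for (cc in c("cn_fzr1", "cn_usp10", "cn_usp13", "cn_skp2")) {
    v <- x[[cc]]
    if (!is.numeric(v)) abort(sprintf("column %s is not numeric", cc))
    bad <- which(!is.na(v) & !(v %in% cn_levels))
    if (length(bad)) {
      abort(sprintf("column %s has invalid copy-number value %s at row %d",
                    cc, format(v[bad[1]]), bad[1]))
    }
    x[[cc]] <- as.integer(v)
  }
  if (any(x$os_time < 0, na.rm = TRUE)) abort("os_time must be >= 0")
  if (!all(x$os_event %in% c(0L, 1L, NA))) abort("os_event must be 0/1")
  if (any(x$positive_nodes < 0, na.rm = TRUE)) abort("positive_nodes must be >= 0")
  x$stage <- factor(x$stage, levels = c("I", "II", "III", "IV", "unknown"),
                    ordered = TRUE)
  x$grade <- factor(as.character(x$grade), levels = c("1", "2", "3", "unknown"),
                    ordered = TRUE)
  x
}

#' Write a cohort table
#'
#' @param cohort A cohort tibble.
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, na = "NA", progress = FALSE)
  invisible(cohort)
}

#' Read a genes-by-samples expression matrix
#'
#' Expects genes as rows with the first column named `gene_id`; all other
#' columns must be fully numeric (an error reports the first offending cell),
#' and duplicate gene ids are rejected.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene-id rownames and sample-id colnames.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!"gene_id" %in% names(x)) abort("first column must be named gene_id")
  for (cc in setdiff(names(x), "gene_id")) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    bad <- which(is.na(v) & !is.na(x[[cc]]))
    if (length(bad)) {
      abort(sprintf("non-numeric cell '%s' at row %d, column %s",
                    x[[cc]][bad[1]], bad[1], cc))
    }
    x[[cc]] <- v
  }
  if (anyDuplicated(x$gene_id)) {
    abort(sprintf("duplicated gene_id '%s'", x$gene_id[duplicated(x$gene_id)][1]))
  }
  m <- as.matrix(x[, setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  if (any(!is.finite(m))) abort("expression matrix contains non-finite values")
  m
}

#' Write a genes-by-samples expression matrix
#'
#' @param expr Numeric matrix with gene-id rownames.
#' @param path Output TSV path (first column `gene_id`).
#' @return The input, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(expr)
}

#' Read reference perturbation profiles from a rank-matrix TSV
#'
#' Wide format: one `gene_id` column plus one column per profile named
#' `drug|cell_line` (or just the drug name), each holding the gene's rank in
#' that profile (1 = most up-regulated). Every column must be a permutation
#' of 1..n_genes.
#'
#' @param path Path to the TSV.
#' @return A tibble with `drug`, `cell_line`, and a `ranked` list-column,
#'   as consumed by [connectivity_screen()].
#' @export
read_reference_profiles <- function(path) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(x)) abort("reference file must have a gene_id column")
  profs <- setdiff(names(x), "gene_id")
  if (length(profs) == 0) abort("reference file has no profile columns")
  entries <- lapply(profs, function(cc) {
    r <- x[[cc]]
    if (!setequal(r, seq_along(r))) {
      abort(sprintf("column %s is not a permutation of ranks 1..%d", cc, length(r)))
    }
    parts <- strsplit(cc, "|", fixed = TRUE)[[1]]
    tibble(drug = parts[1],
           cell_line = if (length(parts) > 1) parts[2] else "unknown",
           ranked = list(x$gene_id[order(r)]))
  })
  bind_rows(entries)
}

#' Write reference perturbation profiles as a rank-matrix TSV
#'
#' @param refs Tibble with `drug`, `cell_line`, `ranked` list-column.
#' @param path Output TSV path.
#' @return The input, invisibly.
#' @export
write_reference_profiles <- function(refs, path) {
  universe <- sort(refs$ranked[[1]])
  cols <- lapply(seq_len(nrow(refs)), function(i) {
    match(universe, refs$ranked[[i]])
  })
  names(cols) <- paste(refs$drug, refs$cell_line, sep = "|")
  df <- as_tibble(c(list(gene_id = universe), cols))
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(refs)
}

#' Read an IC50 table
#'
#' @param path TSV with columns `drug`, `cell_line`, `ln_ic50`.
#' @return A tibble.
#' @export
read_ic50 <- function(path) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  need <- c("drug", "cell_line", "ln_ic50")
  if (!all(need %in% names(x))) {
    abort("IC50 file needs columns drug, cell_line, ln_ic50")
  }
  if (any(!is.finite(x$ln_ic50))) abort("ln_ic50 must be finite")
  x
}
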