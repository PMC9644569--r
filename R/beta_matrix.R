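#' Construct and validate a beta-value matrix
#'
#' A beta matrix is the package's universal measurement container: a numeric
#' matrix of Infinium methylation beta values in `[0, 1]` with CpG probes in
#' rows and samples in columns. Missing values are `NA`, never a sentinel.
#'
#' @param values Numeric matrix with unique rownames (probe IDs) and unique
#'   colnames (sample IDs). Values slightly outside `[0, 1]` (within `1e-9`,
#'   e.g. from rounding on disk) are clamped; anything further out is an error.
#' @return The validated matrix (plain numeric matrix).
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' beta_matrix(m)
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("beta matrix must be a numeric matrix")
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    abort("beta matrix needs at least 1 probe and 1 sample")
  }
  pr <- rownames(values)
  sm <- colnames(values)
  if (is.null(pr) || is.null(sm)) {
    abort("beta matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(pr)) {
    abort(paste0("duplicate probe ID: ", pr[duplicated(pr)][1]))
  }
  if (anyDuplicated(sm)) {
    abort(paste0("duplicate sample ID: ", sm[duplicated(sm)][1]))
  }
  bad <- which(!is.na(values) & (values < -1e-9 | values > 1 + 1e-9))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    abort(sprintf(
      "beta value out of [0,1]: %.6g at probe '%s', sample '%s'",
      values[bad[1]], pr[i[1, 1]], sm[i[1, 2]]
    ))
  }
  values[!is.na(values) & values < 0] <- 0
  values[!is.na(values) & values > 1] <- 1
  values
}

#' Read a beta matrix from delimited text
#'
#' Expects probes in rows and samples in columns: the first column holds probe
#' IDs and the header row holds sample IDs. Empty cells become `NA`.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`. Defaults by file extension
#'   (`.tsv`/`.txt` means tab), otherwise comma.
#' @param transpose If `TRUE` the file is samples-in-rows and is transposed
#'   after reading.
#' @return A validated beta matrix (see [beta_matrix()]).
#' @export
read_beta_matrix <- function(path, dialect = NULL, transpose = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  dialect <- dialect %||% (
    if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "csv"
  )
  dialect <- match.arg(dialect, c("csv", "tsv"))
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  df <- suppressWarnings(reader(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, name_repair = "minimal"
  ))
  if (ncol(df) < 2) abort("malformed header: need a probe-ID column plus >= 1 sample column")
  probes <- df[[1]]
  if (anyNA(probes) || !all(nzchar(probes))) abort("malformed file: missing probe ID")
  sample_ids <- names(df)[-1]
  if (any(!nzchar(sample_ids))) abort("malformed header: empty sample ID")
  m <- vapply(seq_len(ncol(df) - 1L), function(j) {
    raw <- trimws(df[[j + 1L]])
    raw[raw %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("parse error: non-numeric value '%s' at probe '%s', sample '%s'",
                    raw[bad[1]], probes[bad[1]], sample_ids[j]))
    }
    num
  }, numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df), dimnames = list(probes, sample_ids))
  if (transpose) m <- t(m)
  beta_matrix(m)
}

#' Write a beta matrix to delimited text
#'
#' Inverse of [read_beta_matrix()]: probes in rows, first column `probe_id`,
#' one column per sample. Doubles are written with full round-trip precision;
#' `NA` becomes an empty cell.
#'
#' @param m Beta matrix.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  m <- beta_matrix(m)
  df <- tibble::as_tibble(m, rownames = "probe_id")
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a probe mask
#'
#' Plain text, one probe ID per line; `#` starts a comment. Typical use: user
#' supplied lists of cross-reactive, SNP-related, sex-chromosome or non-CpG
#' probes to exclude before any analysis.
#'
#' @param path File path.
#' @return Character vector of unique probe IDs (possibly empty).
#' @export
read_probe_mask <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Drop masked probes from a beta matrix
#'
#' Removes every probe listed in `mask`; mask entries absent from the matrix
#' are ignored. Probe order and the sample set are preserved, and the
#' operation is idempotent. Probe-ID comparison is case-sensitive exact match.
#'
#' @param m Beta matrix.
#' @param mask Character vector of probe IDs to exclude (set semantics).
#' @return The restricted beta matrix.
#' @export
apply_probe_mask <- function(m, mask) {
  m <- beta_matrix(m)
  keep <- !(rownames(m) %in% mask)
  if (!any(keep)) abort("all probes masked")
  m[keep, , drop = FALSE]
}

#' Validate a proportion table
#'
#' A proportion table is a tibble with a `sample_id` column and one numeric
#' column per cell class; entries are non-negative and each row sums to 1
#' within `1e-6`.
#'
#' @param tab Data frame to validate.
#' @return `tab` as a tibble, invisibly validated.
#' @export
validate_proportions <- function(tab) {
  tab <- tibble::as_tibble(tab)
  if (!"sample_id" %in% names(tab)) abort("proportion table needs a sample_id column")
  num <- tab[setdiff(names(tab), c("sample_id", "layer"))]
  if (ncol(num) < 1 || !all(vapply(num, is.numeric, TRUE))) {
    abort("proportion table needs numeric class columns")
  }
  vals <- as.matrix(num)
  if (any(vals < -1e-9, na.rm = TRUE)) abort("negative proportion")
  rs <- rowSums(vals)
  off <- which(abs(rs - 1) > 1e-6)
  if (length(off) > 0) {
    abort(sprintf(
      "proportion rows must sum to 1: sample '%s' sums to %.8f",
      tab$sample_id[off[1]], rs[off[1]]
    ))
  }
  tab
}

#' Write a proportion table
#'
#' Validates (rows must already sum to 1; there is no silent renormalization)
#' and writes CSV. A `layer` column, when present, is kept.
#'
#' @param tab Proportion table (see [validate_proportions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(tab, path) {
  tab <- validate_proportions(tab)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Bundle a beta matrix with per-sample cell-class labels
#'
#' A reference panel holds purified-cell methylation profiles: a beta matrix
#' plus one cell-class label per sample.
#'
#' @param betas Beta matrix (probes x samples).
#' @param labels Named character vector or two-column data frame
#'   (`sample_id`, `class`) assigning every sample exactly one class.
#' @return An object of class `reference_panel`: list with `betas` and
#'   `labels` (named character vector aligned to `colnames(betas)`).
#' @export
reference_panel <- function(betas, labels) {
  betas <- beta_matrix(betas)
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "class") %in% names(labels))) {
      abort("labels data frame needs columns sample_id, class")
    }
    labels <- setNames(as.character(labels$class), labels$sample_id)
  }
  if (is.null(names(labels))) abort("labels must be named by sample ID")
  miss <- setdiff(colnames(betas), names(labels))
  if (length(miss) > 0) {
    abort(paste0("unlabeled samples: ", paste(head(miss, 5), collapse = ", ")))
  }
  labels <- labels[colnames(betas)]
  if (anyNA(labels)) abort("NA class label")
  structure(list(betas = betas, labels = labels), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", nrow(x$betas), " probes x ", ncol(x$betas),
      " samples; classes: ",
      paste(names(table(x$labels)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
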