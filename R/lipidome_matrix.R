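#' Construct a lipidome matrix
#'
#' Samples x lipids abundance matrix with explicit missingness (`NA` marks a
#' lipid not detected in a sample, which is distinct from zero). Units are
#' either absolute amounts (`"pmol"`) or relative abundance (`"mol_percent"`);
#' in mol% every sample's non-missing values sum to 100 (compositional
#' closure).
#'
#' @param values numeric matrix, rows = samples, columns = lipids; both
#'   dimnames required. `NA` = not detected.
#' @param units `"pmol"` or `"mol_percent"`.
#' @return A `"lipidome_matrix"` object (a numeric matrix with a `units`
#'   attribute).
#' @export
lipidome_matrix <- function(values, units = c("pmol", "mol_percent")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x lipids)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs sample row names and lipid column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicated lipid names")
  if (any(values < 0, na.rm = TRUE))
    stop("negative abundances are not allowed")
  if (units == "mol_percent") {
    tot <- rowSums(values, na.rm = TRUE)
    bad <- which(abs(tot - 100) > 1e-9 * 100)
    if (length(bad))
      stop(sprintf("sample '%s' does not close to 100 mol%% (sum = %.6g)",
                   rownames(values)[bad[1]], tot[bad[1]]))
  }
  structure(values, units = units, class = c("lipidome_matrix", "matrix", "array"))
}

#' @export
print.lipidome_matrix <- function(x, ...) {
  cat(sprintf("<lipidome_matrix> %d samples x %d lipids [%s], %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "units"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.lipidome_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    attr(out, "units") <- attr(x, "units")
    class(out) <- class(x)
  }
  out
}

matrix_units <- function(x) attr(x, "units")

#' Normalize absolute amounts to relative abundance (mol%)
#'
#' Divides each sample's non-missing amounts by the sample total and scales to
#' 100. Missing values stay missing.
#'
#' @param matrix a `"lipidome_matrix"` in pmol.
#' @return a `"lipidome_matrix"` in mol_percent.
#' @export
normalize_relative <- function(matrix) {
  stopifnot(inherits(matrix, "lipidome_matrix"))
  if (!identical(matrix_units(matrix), "pmol"))
    stop("input must be in pmol units")
  tot <- rowSums(matrix, na.rm = TRUE)
  n_obs <- rowSums(!is.na(matrix))
  bad <- which(n_obs == 0L | tot <= 0)
  if (length(bad))
    stop(sprintf("sample '%s' has no positive detected lipid; cannot normalize",
                 rownames(matrix)[bad[1]]))
  out <- sweep(unclass(matrix), 1, tot, "/") * 100
  lipidome_matrix(out, units = "mol_percent")
}

#' Filter lipids by detection frequency
#'
#' Keeps lipids observed (non-missing) in at least `min_fraction` of the
#' samples. The sample set is unchanged; with `min_fraction = 1` the result is
#' complete (no missing values). Note this does not re-close mol% values: the
#' retained columns keep their original relative abundances, so downstream
#' log-ratio style statistics are unaffected by the removal.
#'
#' @param matrix a `"lipidome_matrix"`.
#' @param min_fraction required detection fraction in \[0, 1\] (the study-wide
#'   defaults are 0.9 for exploratory analyses and 1.0 for panel selection and
#'   PLS).
#' @return the filtered `"lipidome_matrix"` (units preserved; mol% values are
#'   not re-closed).
#' @export
presence_filter <- function(matrix, min_fraction) {
  stopifnot(inherits(matrix, "lipidome_matrix"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      is.na(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("'min_fraction' must be a single number in [0, 1]")
  frac <- colMeans(!is.na(matrix))
  keep <- frac >= min_fraction
  out <- unclass(matrix)[, keep, drop = FALSE]
  structure(out, units = matrix_units(matrix),
            class = c("lipidome_matrix", "matrix", "array"))
}

#' Write a lipidome matrix to CSV
#'
#' Wide layout: first column `lipid`, remaining columns samples; empty cells
#' mark missing values. The transpose of the in-memory orientation, matching
#' the usual exchange format of lipid quantification tables.
#'
#' @param matrix a `"lipidome_matrix"`.
#' @param path output file.
#' @export
write_lipidome_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "lipidome_matrix"))
  df <- data.frame(lipid = colnames(matrix), t(unclass(matrix)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a lipidome matrix from CSV
#'
#' @param path wide CSV as written by [write_lipidome_csv()] (first column
#'   lipid name, remaining columns sample IDs, empty cell = missing).
#' @param units unit tag of the stored values.
#' @return a `"lipidome_matrix"`.
#' @export
read_lipidome_csv <- function(path, units = c("mol_percent", "pmol")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("lipid table needs a lipid column plus sample columns")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  storage.mode(m) <- "double"
  lipidome_matrix(m, units = units)
}
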