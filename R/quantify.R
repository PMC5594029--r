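#' Identification filter: mass accuracy and blank ratio
#'
#' Retains intensity records whose absolute mass deviation is within
#' `max_ppm` and whose intensity is at least `min_blank_ratio` times the blank
#' control intensity of the same species. Species without a blank entry are
#' treated as blank = 0 and always pass the ratio test.
#'
#' @param records data frame of intensity records with columns `name` (lipid
#'   name), `sample_id`, `intensity` (>= 0), `mass_error_ppm` (signed) and
#'   `ion_mode` (`"positive"`/`"negative"`).
#' @param blanks data frame with columns `name`, `blank_intensity`, or NULL
#'   for no blank information.
#' @param max_ppm mass-accuracy tolerance in ppm (default 2.5).
#' @param min_blank_ratio required intensity-to-blank factor (default 10).
#' @return the retained subset of `records`, plus a `"filter_report"`
#'   attribute: data frame of removed records and the rule that removed them.
#' @export
filter_identifications <- function(records, blanks = NULL,
                                   max_ppm = 2.5, min_blank_ratio = 10) {
  .check_records(records)
  if (!is.numeric(max_ppm) || length(max_ppm) != 1L || max_ppm <= 0)
    stop("'max_ppm' must be a single positive number")
  if (!is.numeric(min_blank_ratio) || length(min_blank_ratio) != 1L ||
      min_blank_ratio <= 0)
    stop("'min_blank_ratio' must be a single positive number")
  blank <- rep(0, nrow(records))
  if (!is.null(blanks)) {
    stopifnot(is.data.frame(blanks),
              all(c("name", "blank_intensity") %in% names(blanks)))
    if (any(blanks$blank_intensity < 0, na.rm = TRUE))
      stop("blank intensities must be >= 0")
    idx <- match(records$name, blanks$name)
    blank[!is.na(idx)] <- blanks$blank_intensity[idx[!is.na(idx)]]
  }
  ppm_ok   <- abs(records$mass_error_ppm) <= max_ppm
  blank_ok <- records$intensity >= min_blank_ratio * blank
  keep <- ppm_ok & blank_ok
  removed <- records[!keep, , drop = FALSE]
  removed$rule <- ifelse(!ppm_ok[!keep], "mass_accuracy", "blank_ratio")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- removed
  out
}

.check_records <- function(records) {
  req <- c("name", "sample_id", "intensity", "mass_error_ppm", "ion_mode")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("'records' must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (any(records$intensity < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  if (!all(records$ion_mode %in% c("positive", "negative")))
    stop("'ion_mode' must be 'positive' or 'negative'")
  invisible(TRUE)
}

# designated internal-standard sets for classes without a same-class standard
IS_SUM_SET <- list(positive = c("LPC", "SM", "PC", "TAG"),
                   negative = c("LPC", "PC", "PE"))

# classes quantified by their own class standard
IS_CLASS_RULE <- c("LPC", "PC", "PE", "SM", "TAG")

#' Internal-standard quantification
#'
#' Converts filtered signal intensities to amounts (pmol). LPC, PC, PE, SM and
#' TAG species are quantified against the same-class internal standard of
#' their ion mode: `amount = intensity / IS_intensity * IS_amount`. All other
#' classes are quantified against the summed intensity of the mode's
#' designated standard set (positive: LPC, SM, PC, TAG; negative: LPC, PC,
#' PE): `amount = intensity / sum(IS intensities) * sum(IS amounts)`. Species
#' not recorded for a sample are missing, never zero.
#'
#' @param records filtered intensity records (see
#'   [filter_identifications()]).
#' @param standards data frame with columns `lipid_class`, `ion_mode`,
#'   `intensity` (> 0) and `amount_pmol` (> 0), one row per spiked standard.
#' @return a `"lipidome_matrix"` in pmol over all samples and species present
#'   in `records`.
#' @export
quantify <- function(records, standards) {
  .check_records(records)
  req <- c("lipid_class", "ion_mode", "intensity", "amount_pmol")
  if (!is.data.frame(standards) || !all(req %in% names(standards)))
    stop("'standards' must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (any(standards$amount_pmol <= 0)) stop("standard amounts must be > 0")
  if (any(standards$intensity <= 0))
    stop("zero or negative internal-standard intensity")
  species <- parse_lipid_name(unique(records$name))
  cls_of <- stats::setNames(species$lipid_class, species$name)
  canon <- stats::setNames(species$name, unique(records$name))
  records$name <- unname(canon[records$name])

  amount_of <- function(name, intensity, mode) {
    cls <- cls_of[[name]]
    if (cls %in% IS_CLASS_RULE) {
      st <- standards[standards$lipid_class == cls & standards$ion_mode == mode, ]
      if (nrow(st) == 0L)
        stop(sprintf("no %s internal standard for %s mode", cls, mode))
      intensity / sum(st$intensity) * sum(st$amount_pmol)
    } else {
      set <- IS_SUM_SET[[mode]]
      st <- standards[standards$lipid_class %in% set & standards$ion_mode == mode, ]
      if (nrow(st) == 0L)
        stop(sprintf("no internal standards (%s) for %s mode",
                     paste(set, collapse = ","), mode))
      intensity / sum(st$intensity) * sum(st$amount_pmol)
    }
  }

  samples <- unique(records$sample_id)
  lipids <- species$name
  m <- matrix(NA_real_, length(samples), length(lipids),
              dimnames = list(samples, lipids))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    m[r$sample_id, r$name] <- amount_of(r$name, r$intensity, r$ion_mode)
  }
  lipidome_matrix(m, units = "pmol")
}

#' Read the wide intensity CSV into long records
#'
#' @param intensities_path wide CSV: first column lipid name, remaining
#'   columns sample IDs; empty cell = not detected.
#' @param meta_path optional CSV with per-lipid columns `name`,
#'   `mass_error_ppm`, `ion_mode`; when absent, mass error defaults to 0 and
#'   the ion mode is inferred from the lipid class (PC/PE/SM/TAG/CE/DAG/Cer/
#'   HexCer and their lyso/ether forms positive, acidic classes negative).
#' @return long data frame of intensity records.
#' @export
read_intensity_csv <- function(intensities_path, meta_path = NULL) {
  df <- utils::read.csv(intensities_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  samples <- names(df)[-1]
  long <- data.frame(
    name = rep(df[[1]], times = length(samples)),
    sample_id = rep(samples, each = nrow(df)),
    intensity = as.numeric(unlist(df[-1], use.names = FALSE)),
    stringsAsFactors = FALSE)
  long <- long[!is.na(long$intensity), , drop = FALSE]
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    idx <- match(long$name, meta$name)
    long$mass_error_ppm <- meta$mass_error_ppm[idx]
    long$ion_mode <- meta$ion_mode[idx]
  } else {
    long$mass_error_ppm <- 0
    cls <- parse_lipid_name(long$name)$lipid_class
    long$ion_mode <- ifelse(
      cls %in% c("PS", "LPS", "PG", "LPG", "PA", "PI", "LPI", "CL"),
      "negative", "positive")
  }
  rownames(long) <- NULL
  long
}
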