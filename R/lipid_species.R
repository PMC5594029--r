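#' Lipid class vocabulary
#'
#' Controlled vocabulary of lipid class tokens handled by the pipeline:
#' glycerophospholipids and their lyso forms, ether lipids (PE-O, PC-O),
#' sphingolipids (SM, Cer, HexCer), neutral lipids (TAG, DAG, CE),
#' cardiolipin (CL) and free cholesterol (FC).
#'
#' @format Character vector of class tokens.
#' @export
LIPID_CLASSES <- c(
  "TAG", "SM", "LPS", "PS", "LPG", "PG", "LPE", "PE", "PE-O", "PA",
  "LPC", "PC", "PC-O", "LPI", "PI", "CL", "CE", "Cer", "HexCer", "DAG", "FC"
)

#' Sphingolipid classes (carry the ";0" / ";1" hydroxylation suffix)
#' @export
SPHINGO_CLASSES <- c("SM", "Cer", "HexCer")

#' Classes without annotated aliphatic chains
#' @keywords internal
CHAINLESS_CLASSES <- "FC"

#' Ether lipid classes (one O-alkyl, one O-acyl chain)
#' @keywords internal
ETHER_CLASSES <- c("PE-O", "PC-O")

# class tokens sorted longest-first so "PE-O" wins over "PE" in alternation
.class_alternation <- function() {
  cls <- LIPID_CLASSES[order(nchar(LIPID_CLASSES), decreasing = TRUE)]
  paste(vapply(cls, function(x) gsub("-", "\\\\-", x), ""), collapse = "|")
}

#' Parse lipid species names
#'
#' Parses sum-composition lipid names of the form `"class [C:DB]"` (e.g.
#' `"PC [32:0]"`), sphingolipid names with a hydroxylation suffix
#' (`"Cer [42:1;0]"`), ether lipids (`"PE-O [36:4]"`), free cholesterol
#' (`"FC"`), and sn-resolved names such as `"PC 16:0/16:0"`, which are
#' collapsed to their sum composition (`"PC [32:0]"`).
#'
#' @param name character vector of lipid names.
#' @return A data frame of class `"lipid_species"` with one row per input and
#'   columns `name` (canonical form), `lipid_class`, `carbons`,
#'   `double_bonds`, `hydroxylations` (NA outside sphingolipids) and `ether`.
#' @examples
#' parse_lipid_name(c("PC [32:0]", "Cer [42:1;0]", "PE-O [36:4]"))
#' parse_lipid_name("PC 16:0/16:0")$name  # "PC [32:0]"
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) == 0L || anyNA(name) || any(!nzchar(name)))
    stop("'name' must be a non-empty character vector without NA/empty entries")
  cls_re <- .class_alternation()
  sum_re <- paste0("^(", cls_re, ") \\[([0-9]+):([0-9]+)(;([0-9]+))?\\]$")
  sn_re  <- paste0("^(", cls_re, ") ([0-9]+:[0-9]+(/[0-9]+:[0-9]+)+)$")

  out <- lapply(name, function(nm) {
    nm <- trimws(nm)
    if (nm %in% CHAINLESS_CLASSES)
      return(list(lipid_class = nm, carbons = NA_integer_,
                  double_bonds = NA_integer_, hydroxylations = NA_integer_,
                  ether = FALSE))
    m <- regmatches(nm, regexec(sum_re, nm))[[1]]
    if (length(m)) {
      cls <- m[2]
      oh  <- if (nzchar(m[5])) as.integer(m[6]) else NA_integer_
      return(.build_species(nm, cls, as.integer(m[3]), as.integer(m[4]), oh))
    }
    m <- regmatches(nm, regexec(sn_re, nm))[[1]]
    if (length(m)) {
      cls <- m[2]
      chains <- strsplit(m[3], "/", fixed = TRUE)[[1]]
      parts <- do.call(rbind, strsplit(chains, ":", fixed = TRUE))
      return(.build_species(nm, cls, sum(as.integer(parts[, 1])),
                            sum(as.integer(parts[, 2])), NA_integer_))
    }
    # diagnose the offending fragment
    head_tok <- sub("^([^ ]+).*$", "\\1", nm)
    if (!head_tok %in% LIPID_CLASSES)
      stop(sprintf("unknown lipid class token '%s' in '%s'", head_tok, nm))
    stop(sprintf(
      "unparseable lipid name '%s': expected '%s [C:DB]'%s or sn-resolved '%s C:DB/C:DB'",
      nm, head_tok, if (head_tok %in% SPHINGO_CLASSES) " with ';0' or ';1' suffix" else "",
      head_tok))
  })
  res <- data.frame(
    name           = vapply(seq_along(out), function(i)
      format_lipid_species(out[[i]]), ""),
    lipid_class    = vapply(out, `[[`, "", "lipid_class"),
    carbons        = vapply(out, `[[`, 1L, "carbons"),
    double_bonds   = vapply(out, `[[`, 1L, "double_bonds"),
    hydroxylations = vapply(out, `[[`, 1L, "hydroxylations"),
    ether          = vapply(out, `[[`, TRUE, "ether"),
    stringsAsFactors = FALSE
  )
  class(res) <- c("lipid_species", "data.frame")
  res
}

.build_species <- function(nm, cls, carbons, db, oh) {
  sphingo <- cls %in% SPHINGO_CLASSES
  if (sphingo && is.na(oh))
    stop(sprintf("sphingolipid '%s' lacks the ';0' or ';1' hydroxylation suffix", nm))
  if (!sphingo && !is.na(oh))
    stop(sprintf("'%s': hydroxylation suffix ';%d' is only valid for %s", nm, oh,
                 paste(SPHINGO_CLASSES, collapse = "/")))
  if (sphingo && !oh %in% c(0L, 1L))
    stop(sprintf("'%s': hydroxylation count must be 0 or 1, got %d", nm, oh))
  if (carbons <= 0L)
    stop(sprintf("'%s': carbon count must be positive", nm))
  list(lipid_class = cls, carbons = carbons, double_bonds = db,
       hydroxylations = if (sphingo) oh else NA_integer_,
       ether = cls %in% ETHER_CLASSES)
}

format_lipid_species <- function(sp) {
  if (sp$lipid_class %in% CHAINLESS_CLASSES) return(sp$lipid_class)
  if (sp$lipid_class %in% SPHINGO_CLASSES)
    sprintf("%s [%d:%d;%d]", sp$lipid_class, sp$carbons, sp$double_bonds,
            sp$hydroxylations)
  else
    sprintf("%s [%d:%d]", sp$lipid_class, sp$carbons, sp$double_bonds)
}

#' Format parsed lipid species back to canonical names
#'
#' Inverse of [parse_lipid_name()] on canonical names:
#' `format_lipid_name(parse_lipid_name(x)) == x` for canonical `x`.
#'
#' @param species a `"lipid_species"` data frame (or any data frame with the
#'   same columns).
#' @return character vector of canonical names.
#' @export
format_lipid_name <- function(species) {
  stopifnot(is.data.frame(species))
  vapply(seq_len(nrow(species)), function(i) {
    format_lipid_species(as.list(species[i, , drop = FALSE]))
  }, "")
}
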