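#' Default lipid catalogue for simulated cohorts
#'
#' Deterministic catalogue of 311 species over the 11 quantified classes of a
#' lung-tissue shotgun screen (CE, Cer, CL, DAG, PC, PE, PG, PI, PS, SM,
#' TAG), enumerated over plausible carbon/double-bond grids. The long-chain
#' PS/PI species used as ageing/emphysema markers (PS [38:4], PI [38:4],
#' PI [38:5], PS [40:4]) are always present.
#'
#' @return data frame with columns `name`, `lipid_class`, `carbons`,
#'   `double_bonds`, `base_log2` (class-level log2 abundance offset).
#' @export
default_lipid_catalogue <- function() {
  grid <- function(cls, carbons, dbs, n, base, sphingo = FALSE) {
    g <- expand.grid(c = carbons, d = dbs)
    g <- g[order(g$c, g$d), ][seq_len(n), ]
    name <- if (sphingo)
      sprintf("%s [%d:%d;%d]", cls, g$c, g$d, rep_len(c(0L, 1L), n))
    else sprintf("%s [%d:%d]", cls, g$c, g$d)
    data.frame(name = name, lipid_class = cls, carbons = g$c,
               double_bonds = g$d, base_log2 = base,
               stringsAsFactors = FALSE)
  }
  cat_df <- rbind(
    grid("PC",  seq(28, 44, 2), 0:5, 45, 6.0),
    grid("PE",  seq(32, 44, 2), 0:5, 35, 5.0),
    grid("TAG", seq(44, 58, 2), 0:7, 60, 4.0),
    grid("SM",  seq(30, 44, 2), 0:3, 30, 4.5, sphingo = TRUE),
    grid("PG",  seq(30, 40, 2), 0:4, 25, 4.0),
    grid("PI",  seq(32, 40, 2), 2:5, 20, 3.5),
    grid("PS",  seq(34, 42, 2), 0:4, 20, 3.0),
    grid("CE",  seq(14, 22, 1), 0:4, 20, 3.0),
    grid("DAG", seq(30, 38, 2), 0:4, 20, 2.5),
    grid("Cer", seq(32, 44, 2), 0:3, 20, 2.0, sphingo = TRUE),
    grid("CL",  seq(64, 72, 2), 4:7, 16, 2.0)
  )
  stopifnot(!anyDuplicated(cat_df$name), nrow(cat_df) == 311L)
  rownames(cat_df) <- NULL
  cat_df
}

#' Configuration of a simulated lipidome cohort
#'
#' The defaults state the cohort the pipeline is designed for: 26 patients
#' contributing 43 tissue samples (17 matched tumour/alveolar pairs, 6
#' tumour-only, 3 control-only), a 311-species catalogue, tumour effects
#' raising TAG/CE/DAG and lowering PG and fully saturated PC, log-normal
#' abundance noise, structured missingness calibrated so roughly 45% of
#' lipids pass a 90% presence filter and 30% a 100% filter, and ageing/
#' emphysema couplings on four long-chain PS/PI species in alveolar tissue.
#'
#' @param n_patients number of patients.
#' @param tissue_counts named counts `both` / `tumour_only` / `control_only`
#'   summing to `n_patients` (set to NULL to draw from `tissue_probs`).
#' @param tissue_probs availability probabilities used when `tissue_counts`
#'   is NULL.
#' @param catalogue lipid catalogue data frame (see
#'   [default_lipid_catalogue()]).
#' @param class_log2fc named log2 fold changes (tumour over alveolar) applied
#'   to whole classes.
#' @param sat_pc_log2fc extra log2 fold change for fully saturated PC
#'   (surfactant species, lower in tumours).
#' @param planted optional data frame (`name`, `log2fc`) of species-level
#'   tumour effects overriding the class effects for those species.
#' @param detect detection model: list with tier fractions `full_tier`
#'   (always detected) and `high_tier` (per-sample probability `high_prob`),
#'   the remainder drawn uniformly from `low_range`; `tissue_dropout`
#'   multiplies detection of non-full-tier TAG/CE in alveolar tissue and PG
#'   in tumour tissue. Use `detect = "all"` for complete detection.
#' @param covariates list: `age_range`, `rho_age_emphysema` (correlation of
#'   age and emphysema grade), `female_prob`, `diagnosis_probs`,
#'   `age_emphysema_targets` (species coupled to ageing/emphysema in
#'   alveolar tissue), `age_emphysema_beta` (log2 shift per SD of the
#'   age/emphysema latent), `inflammation_beta` (log2 shift per inflammation
#'   stage unit on DAG/TAG up and long-chain SM/PG down).
#' @param sigma log2-scale abundance noise SD per lipid and sample.
#' @param sigma_patient SD of the per-patient random intercept (induces
#'   within-patient correlation of matched pairs).
#' @param lipid_spread SD of per-lipid baseline offsets around the class
#'   mean.
#' @return a `"cohort_config"` list.
#' @export
cohort_config <- function(
    n_patients = 26L,
    tissue_counts = c(both = 17L, tumour_only = 6L, control_only = 3L),
    tissue_probs = c(both = 17 / 26, tumour_only = 6 / 26, control_only = 3 / 26),
    catalogue = default_lipid_catalogue(),
    class_log2fc = c(TAG = 2, CE = 2, DAG = 1, PG = -2),
    sat_pc_log2fc = -1,
    planted = NULL,
    detect = list(full_tier = 0.26, high_tier = 0.28, high_prob = 0.95,
                  low_range = c(0.2, 0.9), tissue_dropout = 0.4),
    covariates = list(
      age_range = c(44, 71), rho_age_emphysema = 0.5,
      female_prob = 6 / 26,
      diagnosis_probs = c(ADC = 11 / 26, SCC = 12 / 26, other = 3 / 26),
      age_emphysema_targets = c("PS [38:4]", "PI [38:4]", "PI [38:5]",
                                "PS [40:4]"),
      age_emphysema_beta = 1.2,
      inflammation_beta = 0.5),
    sigma = 0.3, sigma_patient = 0.2, lipid_spread = 1.0) {
  stopifnot(n_patients >= 1L, is.data.frame(catalogue), nrow(catalogue) > 0L,
            sigma > 0, sigma_patient >= 0)
  if (!is.null(tissue_counts) && sum(tissue_counts) != n_patients)
    stop("'tissue_counts' must sum to 'n_patients'")
  if (is.null(tissue_counts) &&
      (any(tissue_probs < 0) || abs(sum(tissue_probs) - 1) > 1e-9))
    stop("'tissue_probs' must be non-negative and sum to 1")
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted), all(c("name", "log2fc") %in% names(planted)))
    bad <- setdiff(planted$name, catalogue$name)
    if (length(bad))
      stop("planted species not in catalogue: ", paste(bad, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients),
                 tissue_counts = tissue_counts, tissue_probs = tissue_probs,
                 catalogue = catalogue, class_log2fc = class_log2fc,
                 sat_pc_log2fc = sat_pc_log2fc, planted = planted,
                 detect = detect, covariates = covariates,
                 sigma = sigma, sigma_patient = sigma_patient,
                 lipid_spread = lipid_spread),
            class = "cohort_config")
}

#' Generate a synthetic lipidome cohort
#'
#' Draws per-lipid baseline log2 abundances around class means, adds tumour
#' class effects, covariate couplings (ageing/emphysema on designated PS/PI
#' species and inflammation on DAG/TAG vs long-chain SM/PG, both in alveolar
#' tissue), a per-patient random intercept and log-normal noise; applies the
#' structured detection model (undetected = missing, e.g. many TAG/CE absent
#' from alveolar tissue and many PG absent from tumours) and closes each
#' sample to 100 mol%. Identical seeds give identical cohorts.
#'
#' @param config a `"cohort_config"`.
#' @param seed integer RNG seed.
#' @return a `"synthetic_cohort"`: list with `matrix` (mol%
#'   `"lipidome_matrix"`), `amounts` (pmol matrix before closure),
#'   `metadata` (per-sample covariates and histology scores) and `truth`
#'   (planted tumour effects, covariate couplings, detection tiers).
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cv <- config$covariates
  catal <- config$catalogue
  L <- nrow(catal)

  ## --- patients ------------------------------------------------------
  np <- config$n_patients
  pid <- sprintf("P%02d", seq_len(np))
  if (!is.null(config$tissue_counts)) {
    avail <- sample(rep(c("both", "tumour_only", "control_only"),
                        times = config$tissue_counts))
  } else {
    avail <- sample(c("both", "tumour_only", "control_only"), np,
                    replace = TRUE, prob = config$tissue_probs)
  }
  z_age <- stats::rnorm(np)
  rho <- cv$rho_age_emphysema
  z_emph <- rho * z_age + sqrt(1 - rho^2) * stats::rnorm(np)
  age <- round(mean(cv$age_range) + z_age * diff(cv$age_range) / 4)
  age <- pmin(pmax(age, cv$age_range[1]), cv$age_range[2])
  emphysema <- pmin(pmax(round(5 + 2.2 * z_emph), 0L), 10L)
  gender <- ifelse(stats::runif(np) < cv$female_prob, "female", "male")
  diagnosis <- sample(names(cv$diagnosis_probs), np, replace = TRUE,
                      prob = cv$diagnosis_probs)
  bmi <- round(stats::rnorm(np, 28, 4), 1)
  py <- round(pmax(stats::rnorm(np, 40, 15), 0))
  gold <- sample(0:3, np, replace = TRUE, prob = c(0.2, 0.4, 0.3, 0.1))
  inflammation <- sample(0:3, np, replace = TRUE, prob = c(0.2, 0.35, 0.3, 0.15))
  macrophages <- sample(0:3, np, replace = TRUE)
  fibrosis <- sample(0:3, np, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  patient_intercept <- stats::rnorm(np, 0, config$sigma_patient)

  ## --- samples -------------------------------------------------------
  tissues <- list(both = c("tumour", "alveolar"), tumour_only = "tumour",
                  control_only = "alveolar")
  meta <- do.call(rbind, lapply(seq_len(np), function(i) {
    tt <- tissues[[avail[i]]]
    data.frame(patient_id = pid[i],
               sample_id = paste0(pid[i], ifelse(tt == "tumour", "T", "A")),
               tissue_type = tt, stringsAsFactors = FALSE)
  }))
  ns <- nrow(meta)
  ip <- match(meta$patient_id, pid)
  meta$diagnosis <- diagnosis[ip]; meta$age <- age[ip]
  meta$bmi <- bmi[ip]; meta$py <- py[ip]; meta$gold <- gold[ip]
  meta$gender <- gender[ip]
  is_tum <- meta$tissue_type == "tumour"
  # tumour histology fractions: vital/stroma/necrosis close to 100%
  g <- matrix(stats::rgamma(ns * 3, shape = c(2.5, 2.5, 1)), ncol = 3,
              byrow = TRUE)
  frac <- round(100 * g / rowSums(g))
  frac[, 2] <- pmin(frac[, 2], 100 - frac[, 1])
  frac[, 3] <- 100 - frac[, 1] - frac[, 2]
  meta$vital_pct <- ifelse(is_tum, frac[, 1], NA)
  meta$stroma_pct <- ifelse(is_tum, frac[, 2], NA)
  meta$necrosis_pct <- ifelse(is_tum, frac[, 3], NA)
  meta$inflammation <- inflammation[ip]
  meta$emphysema <- ifelse(is_tum, NA, emphysema[ip])
  meta$macrophages <- ifelse(is_tum, NA, macrophages[ip])
  meta$fibrosis <- ifelse(is_tum, NA, fibrosis[ip])
  rownames(meta) <- meta$sample_id

  ## --- species-level tumour effects ---------------------------------
  eff <- rep(0, L)
  if (length(config$class_log2fc)) {
    e <- config$class_log2fc[catal$lipid_class]
    e[is.na(e)] <- 0
    eff <- unname(e)
  }
  eff[catal$lipid_class == "PC" & catal$double_bonds == 0] <-
    eff[catal$lipid_class == "PC" & catal$double_bonds == 0] +
    config$sat_pc_log2fc
  if (!is.null(config$planted)) {
    idx <- match(config$planted$name, catal$name)
    eff[idx] <- config$planted$log2fc
  }

  ## --- covariate couplings ------------------------------------------
  beta_ae <- rep(0, L)
  tgt <- intersect(cv$age_emphysema_targets, catal$name)
  beta_ae[match(tgt, catal$name)] <- cv$age_emphysema_beta
  beta_inf <- rep(0, L)
  if (!is.null(cv$inflammation_beta) && cv$inflammation_beta != 0) {
    up <- catal$lipid_class %in% c("DAG", "TAG")
    dn <- (catal$lipid_class %in% c("SM", "PG")) & catal$carbons >=
      stats::ave(catal$carbons, catal$lipid_class, FUN = stats::median)
    beta_inf[up] <- cv$inflammation_beta
    beta_inf[dn] <- -cv$inflammation_beta
  }

  ## --- abundances ----------------------------------------------------
  base <- catal$base_log2 + stats::rnorm(L, 0, config$lipid_spread)
  ae_latent <- (z_age + z_emph) / 2  # shared ageing/emphysema axis
  log2ab <- matrix(rep(base, each = ns), ns, L,
                   dimnames = list(meta$sample_id, catal$name))
  log2ab <- log2ab + patient_intercept[ip]
  log2ab[is_tum, ] <- sweep(log2ab[is_tum, , drop = FALSE], 2, eff, "+")
  alv <- !is_tum
  log2ab[alv, ] <- log2ab[alv, , drop = FALSE] +
    outer(ae_latent[ip[alv]], beta_ae) +
    outer(meta$inflammation[alv] / 3, beta_inf)
  log2ab <- log2ab + matrix(stats::rnorm(ns * L, 0, config$sigma), ns, L)
  amounts <- 2^log2ab

  ## --- detection -----------------------------------------------------
  if (identical(config$detect, "all")) {
    tier <- rep("full", L)
    detp <- matrix(1, ns, L)
  } else {
    d <- config$detect
    tier <- sample(c("full", "high", "low"), L, replace = TRUE,
                   prob = c(d$full_tier, d$high_tier,
                            1 - d$full_tier - d$high_tier))
    tier[match(tgt, catal$name)] <- "full"  # markers must survive filters
    p_l <- ifelse(tier == "full", 1,
                  ifelse(tier == "high", d$high_prob,
                         stats::runif(L, d$low_range[1], d$low_range[2])))
    detp <- matrix(rep(p_l, each = ns), ns, L)
    neutral <- catal$lipid_class %in% c("TAG", "CE") & tier != "full"
    pg <- catal$lipid_class == "PG" & tier != "full"
    detp[alv, neutral] <- detp[alv, neutral] * d$tissue_dropout
    detp[is_tum, pg] <- detp[is_tum, pg] * d$tissue_dropout
  }
  detected <- matrix(stats::runif(ns * L), ns, L) < detp
  amounts[!detected] <- NA_real_

  pm <- lipidome_matrix(amounts, units = "pmol")
  molp <- normalize_relative(pm)

  truth <- list(
    effects = data.frame(name = catal$name, log2fc = eff,
                         stringsAsFactors = FALSE)[eff != 0, ],
    couplings = data.frame(name = tgt,
                           response = "age_emphysema",
                           beta = cv$age_emphysema_beta,
                           stringsAsFactors = FALSE),
    inflammation_beta = beta_inf, tiers = tier, seed = seed)
  structure(list(matrix = molp, amounts = pm, metadata = meta,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples / %d patients, %d lipids (seed %d)\n",
              nrow(x$matrix), length(unique(x$metadata$patient_id)),
              ncol(x$matrix), x$truth$seed))
  invisible(x)
}

#' Convenience preset mirroring the reference cohort dimensions
#'
#' 26 patients, 43 samples (17 matched tumour/alveolar pairs, 6 tumour-only,
#' 3 control-only), 311 catalogue lipids, detection tuned so about 45% of
#' lipids pass the 90% presence filter and about 30% the 100% filter.
#'
#' @param seed integer RNG seed.
#' @return a `"synthetic_cohort"`.
#' @export
paper_like_cohort <- function(seed = 1L) {
  generate_cohort(cohort_config(), seed = seed)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the same formats the analysis consumes: the mol% matrix (wide CSV),
#' the per-sample metadata table, and a ground-truth CSV of planted effects.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lipidome_csv(cohort$matrix, file.path(dir, "molpercent.csv"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$truth$effects, file.path(dir, "truth_effects.csv"),
                   row.names = FALSE)
  invisible(dir)
}
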