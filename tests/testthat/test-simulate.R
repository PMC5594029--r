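test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(cohort_config(), seed = 5)
  b <- generate_cohort(cohort_config(), seed = 5)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$metadata, b$metadata)
  c_ <- generate_cohort(cohort_config(), seed = 6)
  expect_false(identical(unclass(a$matrix), unclass(c_$matrix)))
})

test_that("the paper-like preset has the stated cohort geometry", {
  co <- paper_like_cohort(seed = 2)
  expect_equal(nrow(co$matrix), 43L)
  expect_equal(length(unique(co$metadata$patient_id)), 26L)
  expect_equal(ncol(co$matrix), 311L)
  # matched pairs: same patient, different tissue
  pairs <- split(co$metadata$tissue_type, co$metadata$patient_id)
  n_pairs <- sum(vapply(pairs, length, 1L) == 2)
  expect_equal(n_pairs, 17L)
  for (p in pairs[vapply(pairs, length, 1L) == 2])
    expect_setequal(p, c("tumour", "alveolar"))
  # closure holds for every sample
  expect_equal(unname(rowSums(co$matrix, na.rm = TRUE)), rep(100, 43),
               tolerance = 1e-9)
  # ground truth references catalogue members only
  expect_true(all(co$truth$effects$name %in% co$config$catalogue$name))
  expect_true(all(co$truth$couplings$name %in% co$config$catalogue$name))
})

test_that("detection model lands near the stated presence-filter pass rates", {
  passes <- vapply(1:6, function(s) {
    m <- paper_like_cohort(seed = s + 300)$matrix
    c(mean(colMeans(!is.na(m)) >= 0.9), mean(colMeans(!is.na(m)) == 1))
  }, c(0, 0))
  expect_lt(abs(mean(passes[1, ]) - 0.45), 0.06)
  expect_lt(abs(mean(passes[2, ]) - 0.30), 0.06)
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(n_patients = 10), "sum")
  expect_error(
    cohort_config(planted = data.frame(name = "PC [99:9]", log2fc = 2)),
    "PC \\[99:9\\]")
  expect_error(
    cohort_config(tissue_counts = NULL, tissue_probs = c(0.5, 0.2, 0.2)),
    "sum to 1")
})

test_that("null configuration produces no systematic group differences", {
  cfg <- cohort_config(class_log2fc = NULL, sat_pc_log2fc = 0,
                       detect = "all", sigma_patient = 0,
                       covariates = modifyList(
                         cohort_config()$covariates,
                         list(age_emphysema_beta = 0, inflammation_beta = 0)))
  frac <- vapply(1:10, function(s) {
    co <- generate_cohort(cfg, seed = s + 600)
    lab <- factor(co$metadata$tissue_type)
    nrow(select_panel(co$matrix, lab, 0.01, 0)) / ncol(co$matrix)
  }, 0)
  expect_lt(mean(frac), 0.03)  # ~1% nominal, no systematic inflation
  # and with the fold-change bound nothing is selected
  co <- generate_cohort(cfg, seed = 611)
  expect_equal(nrow(select_panel(co$matrix, factor(co$metadata$tissue_type))), 0L)
})

test_that("planted panels are recovered with correct signs", {
  catal <- default_lipid_catalogue()
  up <- head(catal$name[catal$lipid_class %in% c("TAG", "CE")], 10)
  dn <- head(catal$name[catal$lipid_class == "PG"], 10)
  planted <- data.frame(name = c(up, dn), log2fc = rep(c(2, -2), each = 10))
  cfg <- cohort_config(
    n_patients = 40L,
    tissue_counts = c(both = 0L, tumour_only = 20L, control_only = 20L),
    class_log2fc = NULL, sat_pc_log2fc = 0, planted = planted,
    detect = "all", sigma = 0.3, sigma_patient = 0,
    covariates = modifyList(cohort_config()$covariates,
                            list(age_emphysema_beta = 0, inflammation_beta = 0)))
  ok <- vapply(1:25, function(s) {
    co <- generate_cohort(cfg, seed = s + 700)
    lab <- factor(co$metadata$tissue_type, levels = c("alveolar", "tumour"))
    pan <- select_panel(co$matrix, lab)
    # truth is tumour-over-alveolar; group1 = alveolar flips the sign
    hit <- pan$name %in% planted$name &
      pan$sign_A == -sign(planted$log2fc[match(pan$name, planted$name)])
    sum(hit) >= 18
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("alveolar PLS models recover the planted ageing/emphysema axis", {
  cfg <- cohort_config(
    n_patients = 40L,
    tissue_counts = c(both = 0L, tumour_only = 0L, control_only = 40L))
  res <- vapply(1:10, function(s) {
    co <- generate_cohort(cfg, seed = s + 800)
    m <- presence_filter(co$matrix, 1)
    meta <- co$metadata
    Y <- minmax_scale(encode_metadata(meta, c("age", "emphysema", "bmi")))
    X <- minmax_scale(unclass(m))
    fit <- fit_pls2(X, Y, 3)
    cv <- cross_validate(X, Y, 3, 10, grouping = meta$patient_id, seed = s)
    tg <- intersect(co$truth$couplings$name, rownames(fit$B))
    c(sig_age = unname(cv$significant["age"]),
      sig_emph = unname(cv$significant["emphysema"]),
      sig_bmi = unname(cv$significant["bmi"]),
      signs = all(fit$B[tg, "age"] > 0) && all(fit$B[tg, "emphysema"] > 0),
      prof = cor(fit$B[, "age"], fit$B[, "emphysema"]))
  }, c(0, 0, 0, 0, 0))
  expect_gte(mean(res["sig_age", ]), 0.9)    # coupled responses validate
  expect_gte(mean(res["sig_emph", ]), 0.9)
  expect_lte(mean(res["sig_bmi", ]), 0.1)    # uncoupled response does not
  expect_gte(mean(res["signs", ]), 0.95)     # planted coefficient signs
  # coefficient profiles of the two confounded responses point the same way
  expect_gte(mean(res["prof", ] > 0), 0.9)
  expect_gt(median(res["prof", ]), 0.2)
})

test_that("cohorts round-trip through the CSV writer", {
  co <- generate_cohort(
    cohort_config(n_patients = 6,
                  tissue_counts = c(both = 4, tumour_only = 1, control_only = 1)),
    seed = 9)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  m2 <- read_lipidome_csv(file.path(d, "molpercent.csv"))
  expect_equal(unclass(m2), unclass(co$matrix), tolerance = 1e-6)
  meta2 <- read.csv(file.path(d, "metadata.csv"))
  expect_equal(nrow(meta2), nrow(co$metadata))
})
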