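test_that("min-max scaling maps to [0,1] and inverts exactly", {
  tab <- cbind(a = c(2, 4, 6), b = c(0, 1, 0), cst = c(3, 3, 3))
  expect_warning(sb <- minmax_scale(tab), "cst")
  expect_equal(unname(sb$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(sb$values[, "b"]), c(0, 1, 0))   # binary unchanged
  expect_equal(unname(sb$values[, "cst"]), c(0, 0, 0))
  expect_true(all(sb$values >= 0 & sb$values <= 1))
  inv <- minmax_invert(sb)
  expect_equal(inv[, c("a", "b")], tab[, c("a", "b")], tolerance = 1e-12)
  expect_error(minmax_scale(data.frame(a = 1:3, b = letters[1:3])), "b")
})

test_that("NIPALS PLS2 reaches the exact-fit and OLS limits", {
  set.seed(71)
  n <- 30; p <- 6
  # one latent factor, noiseless: a single component explains everything
  t0 <- rnorm(n)
  X1 <- t0 %*% t(runif(p, 0.5, 2))
  Y1 <- t0 %*% t(c(1, -2))
  f1 <- fit_pls2(X1, Y1, n_components = 1)
  expect_equal(unname(f1$R2[1, ]), c(1, 1), tolerance = 1e-6)
  # full-rank X, all components, single response: OLS equivalence
  X <- matrix(rnorm(n * p), n, p)
  y <- matrix(X %*% rnorm(p) + rnorm(n), n, 1)
  fit <- fit_pls2(X, y, n_components = p)
  b_unstd <- fit$B[, 1] / fit$x_sd * fit$y_sd[1]
  ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(unname(b_unstd), ols, tolerance = 1e-8)
  # t-score orthogonality and unit-norm weights
  g <- crossprod(fit$T)
  expect_equal(g[upper.tri(g)], rep(0, choose(p, 2)), tolerance = 1e-8)
  expect_equal(unname(colSums(fit$W^2)), rep(1, p), tolerance = 1e-12)
})

test_that("deflation reconstructs the standardized X block", {
  set.seed(72)
  X <- matrix(rnorm(20 * 8), 20, 8)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  fit <- fit_pls2(X, Y, n_components = 8)
  z <- scale(X, center = fit$x_mean, scale = fit$x_sd)
  resid <- z - fit$T %*% t(fit$P)
  recon_err <- max(abs(z - (fit$T %*% t(fit$P) + resid)))
  expect_lt(recon_err, 1e-12)
  # with all rank components the residual itself vanishes
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("correlation circle matches a direct Pearson oracle", {
  set.seed(73)
  X <- matrix(rnorm(25 * 7), 25, 7, dimnames = list(NULL, paste0("x", 1:7)))
  Y <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("y1", "y2")))
  fit <- fit_pls2(X, Y, 3)
  cc <- correlation_circle(fit, c(1, 2))
  for (i in seq_len(nrow(cc))) {
    v <- if (cc$block[i] == "X") X[, cc$variable[i]] else Y[, cc$variable[i]]
    expect_equal(cc$t1[i], cor(v, fit$T[, 1]), tolerance = 1e-10)
    expect_equal(cc$t2[i], cor(v, fit$T[, 2]), tolerance = 1e-10)
  }
  expect_true(all(cc$t1^2 + cc$t2^2 <= 1 + 1e-8))  # inside the unit disc
  # a variable equal to t1 sits at (1, 0) (t components are orthogonal)
  fit2 <- fit
  fit2$X_input[, 1] <- fit$T[, 1]
  cc2 <- correlation_circle(fit2, c(1, 2))
  expect_equal(unlist(cc2[1, c("t1", "t2")]), c(t1 = 1, t2 = 0),
               tolerance = 1e-8)
  # zero-variance variable gets NA coordinates, not 0
  Xz <- cbind(X, flat = 7)
  fitz <- suppressWarnings(fit_pls2(Xz, Y, 2))
  ccz <- correlation_circle(fitz, c(1, 2))
  expect_true(all(is.na(ccz[ccz$variable == "flat", c("t1", "t2")])))
})

test_that("cross-validation keeps patients intact and respects definitions", {
  set.seed(74)
  n_pat <- 14
  pats <- rep(sprintf("P%02d", 1:n_pat), each = 2)  # matched pairs
  n <- length(pats)
  X <- matrix(rnorm(n * 10), n, 10)
  Y <- matrix(X[, 1] + rnorm(n, 0, 0.5), n, 1)
  seg <- assign_segments(pats, n_segments = 7, seed = 5)
  # every patient in exactly one segment; sizes differ by at most 1
  expect_true(all(tapply(seg, pats, function(s) length(unique(s))) == 1))
  sz <- table(tapply(seg, pats, unique))
  expect_lte(diff(range(sz)), 1)
  expect_error(assign_segments(pats, n_segments = 15), "14 patients")
  cv <- cross_validate(X, Y, n_components = 2, n_segments = 7,
                       grouping = pats, seed = 5)
  expect_equal(dim(cv$Q2), c(2L, 1L))
  expect_identical(cv$threshold, 0.0975)
  expect_identical(unname(cv$significant), unname(apply(cv$Q2, 2, max) >= 0.0975))
  # Q2 <= R2 in expectation over seeds (CV never beats the apparent fit)
  full <- fit_pls2(X, Y, 2)
  q2_1 <- mean(vapply(1:10, function(s)
    cross_validate(X, Y, 2, 7, grouping = pats, seed = s)$Q2[1, 1], 0))
  expect_lt(q2_1, full$R2[1, 1])
})

test_that("categorical responses are evaluated by Mann-Whitney on fitted values", {
  set.seed(75)
  n <- 30
  grp <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 12), n, 12)
  X[, 1:5] <- X[, 1:5] + grp * 1.5       # planted two-level effect
  Y <- cbind(pheno = grp, noise = rnorm(n))
  fit <- fit_pls2(X, Y, 2)
  ev <- evaluate_categorical(fit, "pheno", c(0, 1))
  expect_lt(ev$p, 0.05)
  expect_error(evaluate_categorical(fit, "absent"), "not among")
  # no separation: identical fitted values for both levels give p = 1
  fit0 <- fit_pls2(matrix(rnorm(n * 4), n, 4), Y, 1)
  fit0$fitted[, "pheno"] <- 0.5
  expect_equal(evaluate_categorical(fit0, "pheno", c(0, 1))$p, 1)
})

test_that("metadata encoding preserves order and unit range", {
  meta <- data.frame(
    gender = c("male", "female", "male", "female"),
    inflammation = c(0L, 3L, 1L, 2L),
    gold = factor(c("0", "1", "2", "3"), ordered = TRUE),
    age = c(44, 71, 60, 55))
  enc <- encode_metadata(meta, c("gender", "inflammation", "gold", "age"))
  expect_setequal(unique(enc[, "gender"]), c(0, 1))
  expect_equal(unname(enc[, "inflammation"]), meta$inflammation)  # passthrough
  expect_equal(unname(enc[, "gold"]), c(0, 1, 2, 3) / 3)
  expect_equal(unname(enc[, "age"]), meta$age)
})
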