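#' Min-max scale a block of variables to [0, 1]
#'
#' Per-variable affine map `x' = (x - min) / (max - min)`. Constant columns
#' map to all-zero with a warning. Original minima and maxima are retained so
#' the transform is invertible.
#'
#' @param table numeric data frame or matrix, samples x variables;
#'   categorical variables must already be numerically encoded (see
#'   [encode_metadata()]).
#' @param kinds optional character vector (`"continuous"`/`"categorical"`)
#'   per variable, carried along as annotation.
#' @return a `"scaled_block"`: list with `values` (matrix in \[0,1\]), `min`,
#'   `max`, `kinds`.
#' @export
minmax_scale <- function(table, kinds = NULL) {
  if (is.data.frame(table)) {
    bad <- names(table)[!vapply(table, is.numeric, TRUE)]
    if (length(bad))
      stop("non-numeric column(s): ", paste(bad, collapse = ", "))
    table <- as.matrix(table)
  }
  if (!is.numeric(table)) stop("'table' must be numeric")
  if (anyNA(table)) {
    idx <- which(is.na(table), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %s, column %s: drop incomplete samples first",
                 rownames(table)[idx[1]] %||% idx[1],
                 colnames(table)[idx[2]] %||% idx[2]))
  }
  mins <- apply(table, 2, min)
  maxs <- apply(table, 2, max)
  rng <- maxs - mins
  const <- rng == 0
  if (any(const)) {
    warning("constant column(s) mapped to 0: ",
            paste(colnames(table)[const], collapse = ", "))
    rng[const] <- 1
  }
  vals <- sweep(sweep(table, 2, mins, "-"), 2, rng, "/")
  vals[, const] <- 0
  structure(list(values = vals, min = mins, max = maxs,
                 kinds = kinds %||% rep("continuous", ncol(table))),
            class = "scaled_block")
}

#' Invert a min-max scaling
#' @param block a `"scaled_block"`.
#' @param values matrix in the scaled space (default: the block's own values).
#' @return matrix on the original scale.
#' @export
minmax_invert <- function(block, values = block$values) {
  stopifnot(inherits(block, "scaled_block"))
  sweep(sweep(values, 2, block$max - block$min, "*"), 2, block$min, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.block_values <- function(x) {
  if (inherits(x, "scaled_block")) x$values
  else if (is.matrix(x)) x
  else as.matrix(x)
}

# centre and (optionally) unit-variance scale; zero-variance columns stay 0
.standardize <- function(m, center = TRUE, scale = TRUE) {
  mu <- if (center) colMeans(m) else rep(0, ncol(m))
  z <- sweep(m, 2, mu, "-")
  sds <- rep(1, ncol(m))
  if (scale) {
    sds <- apply(z, 2, stats::sd)
    sds[sds == 0] <- 1
    z <- sweep(z, 2, sds, "/")
  }
  list(z = z, mean = mu, sd = sds)
}

#' Fit a PLS2 regression by NIPALS
#'
#' Two-block partial least squares with multivariate response. Both blocks
#' are column-centred and scaled to unit variance internally (after any
#' min-max scaling the caller applied). Components are extracted by the
#' NIPALS iteration: `w = X'u / |X'u|`, `t = Xw`, `c = Y't / t't`,
#' `u = Yc / c'c` to convergence, followed by deflation of X (loadings `p`)
#' and Y. Regression coefficients in the standardized space are
#' `B = W (P'W)^-1 C'`.
#'
#' @param X,Y `"scaled_block"`s or numeric matrices (samples x variables);
#'   same row count.
#' @param n_components number of latent components (default 3).
#' @param center,scale internal standardization toggles (defaults TRUE).
#' @param tol,max_iter NIPALS convergence controls.
#' @return a `"pls_model"`: scores `T` (samples x H), weights `W`, X-loadings
#'   `P`, Y-loadings `C`, standardized coefficients `B`, per-response
#'   cumulative `R2` (H x q), fitted values on the input scale, residual sums
#'   of squares `RSS` ((H+1) x q, first row about the mean), plus the
#'   standardization parameters needed for prediction.
#' @export
fit_pls2 <- function(X, Y, n_components = 3L, center = TRUE, scale = TRUE,
                     tol = 1e-10, max_iter = 500L) {
  Xm <- .block_values(X); Ym <- .block_values(Y)
  if (is.null(colnames(Ym))) colnames(Ym) <- paste0("Y", seq_len(ncol(Ym)))
  if (is.null(colnames(Xm))) colnames(Xm) <- paste0("X", seq_len(ncol(Xm)))
  if (nrow(Xm) != nrow(Ym)) stop("X and Y must have the same samples")
  n <- nrow(Xm); p <- ncol(Xm); q <- ncol(Ym)
  H <- min(n_components, n - 1L, p)
  sx <- .standardize(Xm, center, scale)
  sy <- .standardize(Ym, center, scale)
  E <- sx$z; F_ <- sy$z
  W <- matrix(0, p, H); P <- matrix(0, p, H)
  Tm <- matrix(0, n, H); C <- matrix(0, q, H)
  RSS <- matrix(0, H + 1L, q,
                dimnames = list(NULL, colnames(Ym)))
  RSS[1L, ] <- colSums(F_^2)
  h_done <- 0L
  for (h in seq_len(H)) {
    if (sum(F_^2) < 1e-12 || sum(E^2) < 1e-12) {
      message(sprintf("PLS residual exhausted; stopping after %d component(s)",
                      h_done))
      break
    }
    u <- F_[, which.max(apply(F_, 2, stats::var)), drop = TRUE]
    t_old <- rep(0, n)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t_ <- drop(E %*% w)
      cc <- drop(crossprod(F_, t_)) / sum(t_^2)
      u <- drop(F_ %*% cc) / sum(cc^2)
      if (sqrt(sum((t_ - t_old)^2)) < tol * max(1, sqrt(sum(t_^2)))) {
        conv <- TRUE; break
      }
      t_old <- t_
    }
    if (!conv) {
      # the NIPALS fixed point is the leading left singular vector of E'F;
      # when the top two singular values nearly tie the power iteration
      # oscillates, so resolve it directly
      sv <- svd(crossprod(E, F_), nu = 1L, nv = 0L)
      if (sv$d[1] < 1e-12)
        stop(sprintf("component %d is degenerate: no X/Y covariance left", h))
      w <- drop(sv$u)
      t_ <- drop(E %*% w)
      cc <- drop(crossprod(F_, t_)) / sum(t_^2)
    }
    # deterministic sign: largest-magnitude weight positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; t_ <- -t_; cc <- -cc
    }
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - tcrossprod(t_, cc)
    W[, h] <- w; P[, h] <- p_; Tm[, h] <- t_; C[, h] <- cc
    RSS[h + 1L, ] <- colSums(F_^2)
    h_done <- h
  }
  if (h_done == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(h_done), drop = FALSE]
  P <- P[, seq_len(h_done), drop = FALSE]
  Tm <- Tm[, seq_len(h_done), drop = FALSE]
  C <- C[, seq_len(h_done), drop = FALSE]
  RSS <- RSS[seq_len(h_done + 1L), , drop = FALSE]
  R2 <- 1 - sweep(RSS[-1L, , drop = FALSE], 2, RSS[1L, ], "/")
  # coefficients per component count, standardized space
  B_list <- lapply(seq_len(h_done), function(h) {
    Wh <- W[, seq_len(h), drop = FALSE]
    Ph <- P[, seq_len(h), drop = FALSE]
    Ch <- C[, seq_len(h), drop = FALSE]
    Wh %*% solve(crossprod(Ph, Wh), t(Ch))
  })
  B <- B_list[[h_done]]
  dimnames(B) <- list(colnames(Xm), colnames(Ym))
  fitted_std <- sx$z %*% B
  fitted <- sweep(sweep(fitted_std, 2, sy$sd, "*"), 2, sy$mean, "+")
  structure(list(
    n_components = h_done, T = Tm, W = W, P = P, C = C,
    B = B, B_per_h = B_list, R2 = R2, RSS = RSS,
    fitted = fitted, X_input = Xm, Y_input = Ym,
    x_mean = sx$mean, x_sd = sx$sd, y_mean = sy$mean, y_sd = sy$sd,
    center = center, scale = scale),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d predictors, %d response(s)\n",
              x$n_components, nrow(x$B), ncol(x$B)))
  cat("cumulative R2 (last component):\n")
  print(round(x$R2[x$n_components, ], 4))
  invisible(x)
}

#' Predict responses from a fitted PLS2 model
#'
#' @param object a `"pls_model"`.
#' @param newdata matrix on the same scale as the training X input.
#' @param n_components number of components to use (default: all fitted).
#' @param ... unused.
#' @return matrix of predicted responses on the Y input scale.
#' @export
predict.pls_model <- function(object, newdata,
                              n_components = object$n_components, ...) {
  newdata <- .block_values(newdata)
  h <- min(n_components, object$n_components)
  z <- sweep(sweep(newdata, 2, object$x_mean, "-"), 2, object$x_sd, "/")
  pred_std <- z %*% object$B_per_h[[h]]
  sweep(sweep(pred_std, 2, object$y_sd, "*"), 2, object$y_mean, "+")
}

#' Partition patients into cross-validation segments
#'
#' Patients (not samples) are shuffled and split into `n_segments` segments
#' whose sizes differ by at most one, so matched samples from one patient are
#' never split across training and validation.
#'
#' @param patients patient identifier per sample.
#' @param n_segments number of segments (default 10).
#' @param seed RNG seed for the shuffle.
#' @return integer segment id per sample.
#' @export
assign_segments <- function(patients, n_segments = 10L, seed = NULL) {
  ids <- unique(patients)
  if (length(ids) < n_segments)
    stop(sprintf("only %d patients for %d segments", length(ids), n_segments))
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(ids)
  sizes <- rep(length(ids) %/% n_segments, n_segments)
  extra <- length(ids) %% n_segments
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  seg_of <- rep(seq_len(n_segments), times = sizes)
  names(seg_of) <- shuffled
  unname(seg_of[as.character(patients)])
}

#' Patient-grouped cross-validation with Q2
#'
#' Ten-segment (default) cross-validation of a PLS2 model. All samples of a
#' patient share one segment. For each held-out segment a model is fit on
#' the remaining segments and predicts the held-out responses; per response
#' and component, `Q2_h = 1 - PRESS_h / RSS_(h-1)` where PRESS accumulates
#' squared prediction errors over held-out segments and RSS comes from the
#' full-data model (RSS_0 = sum of squares about the mean). A response is
#' flagged significant when any component's Q2 is >= 0.0975.
#'
#' @param X,Y `"scaled_block"`s or matrices over the same samples.
#' @param n_components components to evaluate (default 3).
#' @param n_segments number of segments (default 10).
#' @param grouping patient id per sample (default: each sample its own
#'   patient).
#' @param seed RNG seed for segment assignment.
#' @param center,scale standardization toggles passed to [fit_pls2()].
#' @return a `"cv_report"`: list with `segments` (per sample), `Q2`
#'   (components x responses), `Q2_total` (pooled over responses),
#'   `significant` (per response), `threshold`.
#' @export
cross_validate <- function(X, Y, n_components = 3L, n_segments = 10L,
                           grouping = NULL, seed = NULL,
                           center = TRUE, scale = TRUE) {
  Xm <- .block_values(X); Ym <- .block_values(Y)
  if (is.null(colnames(Ym))) colnames(Ym) <- paste0("Y", seq_len(ncol(Ym)))
  n <- nrow(Xm)
  if (n_segments < 2L) stop("'n_segments' must be >= 2")
  grouping <- grouping %||% seq_len(n)
  if (length(grouping) != n) stop("'grouping' must have one entry per sample")
  seg <- assign_segments(grouping, n_segments, seed)
  full <- fit_pls2(Xm, Ym, n_components, center = center, scale = scale)
  H <- full$n_components
  press <- matrix(0, H, ncol(Ym), dimnames = list(NULL, colnames(Ym)))
  for (s in seq_len(n_segments)) {
    tr <- seg != s; te <- !tr
    fit <- fit_pls2(Xm[tr, , drop = FALSE], Ym[tr, , drop = FALSE],
                    n_components, center = center, scale = scale)
    for (h in seq_len(H)) {
      hh <- min(h, fit$n_components)
      pred <- predict(fit, Xm[te, , drop = FALSE], n_components = hh)
      press[h, ] <- press[h, ] + colSums((Ym[te, , drop = FALSE] - pred)^2)
    }
  }
  rss_prev <- full$RSS[seq_len(H), , drop = FALSE]  # rows h-1 = 0..H-1
  # RSS is in the standardized space; rescale to the Y input space used by PRESS
  rss_prev <- sweep(rss_prev, 2, full$y_sd^2, "*")
  Q2 <- 1 - press / rss_prev
  press_tot <- rowSums(press)
  rss_tot <- rowSums(rss_prev)
  structure(list(segments = seg, Q2 = Q2,
                 Q2_total = 1 - press_tot / rss_tot,
                 significant = apply(Q2, 2, function(col) any(col >= 0.0975)),
                 threshold = 0.0975, n_segments = n_segments),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d segments; Q2 threshold %.4f\n",
              x$n_segments, x$threshold))
  best <- apply(x$Q2, 2, max)
  for (k in seq_along(best))
    cat(sprintf("  %-16s max Q2 = %+.3f %s\n", colnames(x$Q2)[k], best[k],
                if (x$significant[k]) "*" else ""))
  invisible(x)
}

#' Mann-Whitney evaluation of a categorical response
#'
#' Compares the model's fitted values for a categorical response between two
#' of its observed levels: if the lipidome carries the phenotype, fitted
#' values separate the levels.
#'
#' @param model a `"pls_model"` whose Y included `response`.
#' @param response response column name.
#' @param level_pair two values of the (encoded) response to contrast;
#'   default: the two most frequent levels.
#' @return list with `fitted` (per-sample fitted values for the two levels),
#'   `levels`, `U`, `p` (two-sided Mann-Whitney).
#' @export
evaluate_categorical <- function(model, response, level_pair = NULL) {
  stopifnot(inherits(model, "pls_model"))
  if (!response %in% colnames(model$Y_input))
    stop(sprintf("'%s' was not among the model responses", response))
  y <- model$Y_input[, response]
  f <- model$fitted[, response]
  if (is.null(level_pair)) {
    tab <- sort(table(y), decreasing = TRUE)
    if (length(tab) < 2L) stop("response has fewer than two levels")
    level_pair <- as.numeric(names(tab)[1:2])
  }
  i1 <- y == level_pair[1]; i2 <- y == level_pair[2]
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("each contrasted level needs at least 2 samples")
  mw <- mann_whitney_u(f[i1], f[i2])
  list(fitted = list(f[i1], f[i2]), levels = level_pair, U = mw$U, p = mw$p)
}

#' Correlation circle coordinates
#'
#' Pearson correlation of every X and Y variable with the chosen pair of
#' latent t-components; by Cauchy-Schwarz all coordinates lie in the unit
#' disc. Zero-variance variables get NA coordinates.
#'
#' @param model a `"pls_model"`.
#' @param components pair of component indices (default `c(1, 2)`).
#' @return data frame: `variable`, `block` ("X"/"Y"), and one coordinate per
#'   chosen component.
#' @export
correlation_circle <- function(model, components = c(1L, 2L)) {
  stopifnot(inherits(model, "pls_model"))
  if (any(components > model$n_components))
    stop("requested component was not fitted")
  Tm <- model$T[, components, drop = FALSE]
  corr_block <- function(m) {
    apply(m, 2, function(v) {
      if (stats::sd(v) == 0) return(rep(NA_real_, ncol(Tm)))
      apply(Tm, 2, function(t_) stats::cor(v, t_))
    })
  }
  cx <- t(corr_block(model$X_input))
  cy <- t(corr_block(model$Y_input))
  out <- data.frame(
    variable = c(colnames(model$X_input), colnames(model$Y_input)),
    block = c(rep("X", ncol(model$X_input)), rep("Y", ncol(model$Y_input))),
    stringsAsFactors = FALSE)
  coords <- rbind(cx, cy)
  colnames(coords) <- paste0("t", components)
  cbind(out, coords)
}

#' Encode clinical metadata as numeric responses
#'
#' Two-level categories (e.g. gender) map to 0/1 in level order; ordered
#' multi-level scores (inflammation 0-3, emphysema 0-10, GOLD stage) map to
#' level/max preserving order; the GOLD value for patients without COPD is 0.
#' Continuous covariates pass through. Samples with NA in a requested
#' response should be dropped by the caller for that model.
#'
#' @param metadata data frame of per-sample covariates.
#' @param responses columns to encode.
#' @return numeric matrix, samples x responses.
#' @export
encode_metadata <- function(metadata, responses) {
  stopifnot(is.data.frame(metadata), all(responses %in% names(metadata)))
  enc <- lapply(responses, function(v) {
    col <- metadata[[v]]
    if (is.numeric(col)) return(col)
    f <- as.factor(col)
    if (nlevels(f) == 2L) return(as.numeric(f) - 1)
    # ordered multi-level: numeric level index scaled to [0, 1]
    (as.numeric(f) - 1) / (nlevels(f) - 1)
  })
  m <- do.call(cbind, enc)
  dimnames(m) <- list(rownames(metadata) %||% metadata$sample_id, responses)
  m
}
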