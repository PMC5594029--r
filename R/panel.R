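#' Mann-Whitney U test
#'
#' Rank-sum test of two independent groups. The reported statistic is
#' U1, the number of (group1, group2) pairs where the group1 value is larger,
#' counting ties as 1/2. For combined n <= 12 without ties the two-sided p
#' value is exact, from full enumeration of the permutation distribution of
#' U; otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param group1,group2 numeric vectors (non-empty).
#' @return list with `U` (U1 statistic), `p` (two-sided), `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(group1, group2) {
  if (length(group1) == 0L || length(group2) == 0L)
    stop("both groups must be non-empty")
  x <- as.numeric(group1); y <- as.numeric(group2)
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n <= 12L && !ties) {
    # exact permutation distribution of U1 over all C(n, n1) labelings
    rr <- seq_len(n)  # no ties: ranks are 1..n
    combs <- utils::combn(n, n1)
    us <- colSums(matrix(rr[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(us <= u1 + 1e-9)
    p_ge <- mean(us >= u1 - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = u1, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tab <- table(r)
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u1, p = 1, method = "normal"))
  z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
  list(U = u1, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Select a discriminative lipid panel
#'
#' Candidate lipids are tested between the two groups by a two-sided Welch
#' t-test on log2 relative abundance; the fold change is computed on the
#' group means of relative abundance (group1 over group2) and
#' log2-transformed. A lipid joins the panel when `p < p_threshold` and
#' `|log2FC| > log2fc_threshold` (strict inequalities). `sign_A = +1` when
#' the lipid is higher in group1, `-1` when lower, per the fold-change
#' direction. The full-cohort mean of log2 abundance of each member is stored
#' for score centring.
#'
#' @param matrix complete `"lipidome_matrix"` (apply
#'   `presence_filter(matrix, 1)` first); values must be positive.
#' @param labels factor-like vector over samples with exactly two levels;
#'   the first level encountered (or first factor level) is "group1".
#' @param p_threshold significance bound (default 0.01).
#' @param log2fc_threshold absolute log2 fold-change bound (default 1,
#'   i.e. twofold).
#' @return a `"discrimination_panel"`: data frame with columns `name`,
#'   `sign_A`, `log2fc`, `p`, `reference_mean`, plus attributes recording the
#'   thresholds and group levels.
#' @export
select_panel <- function(matrix, labels, p_threshold = 0.01,
                         log2fc_threshold = 1) {
  stopifnot(inherits(matrix, "lipidome_matrix"))
  if (anyNA(matrix))
    stop("panel selection requires a complete matrix; apply presence_filter(matrix, 1)")
  if (any(matrix <= 0))
    stop("panel selection requires strictly positive abundances (log2 transform)")
  labels <- as.factor(labels)
  if (length(labels) != nrow(matrix))
    stop("'labels' must have one entry per sample")
  if (nlevels(droplevels(labels)) != 2L) stop("exactly two groups required")
  labels <- droplevels(labels)
  g1 <- levels(labels)[1]; g2 <- levels(labels)[2]
  if (min(table(labels)) < 2L)
    stop("each group needs at least 2 samples")
  lx <- log2(unclass(matrix))
  i1 <- labels == g1; i2 <- labels == g2
  pvals <- vapply(seq_len(ncol(lx)), function(j)
    stats::t.test(lx[i1, j], lx[i2, j])$p.value, 0)
  log2fc <- log2(colMeans(unclass(matrix)[i1, , drop = FALSE]) /
                 colMeans(unclass(matrix)[i2, , drop = FALSE]))
  sel <- pvals < p_threshold & abs(log2fc) > log2fc_threshold
  panel <- data.frame(
    name = colnames(matrix)[sel],
    sign_A = ifelse(log2fc[sel] > 0, 1L, -1L),
    log2fc = unname(log2fc[sel]),
    p = pvals[sel],
    reference_mean = unname(colMeans(lx)[sel]),
    stringsAsFactors = FALSE)
  structure(panel,
            p_threshold = p_threshold, log2fc_threshold = log2fc_threshold,
            group1 = g1, group2 = g2,
            class = c("discrimination_panel", "data.frame"))
}

#' Tissue discrimination score
#'
#' Per-sample score `S = sum_i A_i * c_i` over the panel lipids, where
#' `c_i` is the log2 relative abundance of lipid i centred on the panel's
#' reference mean and `A_i` is the fold-change sign (+1 if higher in group1).
#' Scored on the cohort the panel was centred on, the scores sum to zero.
#'
#' @param matrix `"lipidome_matrix"`; every panel lipid must be detected
#'   (non-missing, positive) in every scored sample.
#' @param panel a `"discrimination_panel"` from [select_panel()] (or a data
#'   frame with `name`, `sign_A`, `reference_mean`).
#' @param labels optional group labels carried into the result for ROC
#'   evaluation.
#' @return a `"score_result"`: data frame with `sample_id`, `score` and
#'   (optionally) `label`.
#' @export
compute_score <- function(matrix, panel, labels = NULL) {
  stopifnot(inherits(matrix, "lipidome_matrix"), is.data.frame(panel))
  if (nrow(panel) == 0L) stop("empty panel")
  miss <- setdiff(panel$name, colnames(matrix))
  if (length(miss))
    stop("panel lipids absent from matrix: ", paste(miss, collapse = ", "))
  sub <- unclass(matrix)[, panel$name, drop = FALSE]
  if (anyNA(sub)) {
    idx <- which(is.na(sub), arr.ind = TRUE)[1, ]
    stop(sprintf("panel lipid '%s' missing in sample '%s'",
                 colnames(sub)[idx[2]], rownames(sub)[idx[1]]))
  }
  cmat <- sweep(log2(sub), 2, panel$reference_mean, "-")
  s <- drop(cmat %*% panel$sign_A)
  out <- data.frame(sample_id = rownames(matrix), score = unname(s),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(matrix))
    out$label <- as.character(labels)
  }
  class(out) <- c("score_result", "data.frame")
  out
}

#' ROC curve and AUC of a score
#'
#' Threshold-free ROC over all score cutoffs with half-credit for ties:
#' `AUC = U / (n1 * n2)` where U is the Mann-Whitney statistic of the
#' favourable direction. The orientation (which group scores higher) is
#' chosen so the reported AUC is >= 0.5 and is stated in the result.
#'
#' @param scores a `"score_result"` with a `label` column, or a numeric
#'   vector combined with `labels`.
#' @param labels two-group labels (when `scores` is a plain vector).
#' @return list with `curve` (data frame `threshold`, `sensitivity`,
#'   `specificity`), `auc`, `positive` (the higher-scoring group),
#'   `mwu_p` (two-sided Mann-Whitney p value).
#' @export
roc_auc <- function(scores, labels = NULL) {
  if (inherits(scores, "score_result")) {
    if (is.null(labels)) {
      if (is.null(scores$label)) stop("score_result carries no labels")
      labels <- scores$label
    }
    scores <- scores$score
  }
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("ROC needs exactly two classes")
  ga <- levels(labels)[1]; gb <- levels(labels)[2]
  xa <- scores[labels == ga]; xb <- scores[labels == gb]
  mw <- mann_whitney_u(xa, xb)
  auc_a <- mw$U / (length(xa) * length(xb))  # P(score_a > score_b) + ties/2
  positive <- if (auc_a >= 0.5) ga else gb
  auc <- max(auc_a, 1 - auc_a)
  pos <- labels == positive
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), 0)
  list(curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec),
       auc = auc, positive = positive, mwu_p = mw$p)
}
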