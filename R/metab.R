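# Targeted-metabolomics preprocessing (missingness / RSD filters, half-min
# imputation, log transform, Pareto scaling), NIPALS PLS-DA with VIP scores
# and cross-validated accuracy, and pairwise group contrasts combining a
# per-comparison VIP with a two-sample t-test on log intensities.

#' Preprocess a metabolite intensity panel
#'
#' Drops metabolites missing in more than `missing_cutoff` of samples, drops
#' constant rows and rows with relative standard deviation (sd/mean on the
#' raw scale) above `rsd_cutoff`, imputes remaining missing cells with half
#' the metabolite's observed minimum, and log2-transforms. Pareto scaling is
#' applied separately (only for PLS-DA) by [pareto_scale()].
#'
#' @param panel Positive intensity matrix, metabolites x samples, `NA` for
#'   missing.
#' @param missing_cutoff Maximum tolerated missing proportion (default 0.20).
#' @param rsd_cutoff Maximum tolerated RSD on the raw scale (default 3.0).
#' @return Log2 intensity matrix without missing values; attribute `record`
#'   lists the dropped metabolites by reason.
#' @export
preprocess_metabolites <- function(panel, missing_cutoff = 0.20,
                                   rsd_cutoff = 3.0) {
  if (any(panel <= 0, na.rm = TRUE))
    stop("input error: intensities must be positive where observed")
  miss_prop <- rowMeans(is.na(panel))
  drop_missing <- rownames(panel)[miss_prop > missing_cutoff]
  keep <- panel[miss_prop <= missing_cutoff, , drop = FALSE]
  obs_sd <- apply(keep, 1, stats::sd, na.rm = TRUE)
  obs_mean <- rowMeans(keep, na.rm = TRUE)
  rsd <- obs_sd / obs_mean
  drop_const <- rownames(keep)[obs_sd == 0]
  drop_rsd <- rownames(keep)[obs_sd > 0 & rsd > rsd_cutoff]
  keep <- keep[obs_sd > 0 & rsd <= rsd_cutoff, , drop = FALSE]
  if (nrow(keep) == 0) stop("input error: no metabolites left after filtering")
  for (i in seq_len(nrow(keep))) {
    nas <- is.na(keep[i, ])
    if (any(nas)) keep[i, nas] <- min(keep[i, !nas]) / 2
  }
  out <- log2(keep)
  attr(out, "record") <- list(dropped_missing = drop_missing,
                              dropped_constant = drop_const,
                              dropped_rsd = drop_rsd,
                              missing_cutoff = missing_cutoff,
                              rsd_cutoff = rsd_cutoff,
                              imputation = "half-minimum")
  out
}

#' Pareto scaling
#'
#' Per metabolite: centre and divide by the square root of the standard
#' deviation, damping the dominance of high-abundance metabolites while
#' keeping some of the original variance structure (the variance of a scaled
#' row equals the sd of the original row).
#'
#' @param m Log-scale matrix without missing values.
#' @return Scaled matrix.
#' @export
pareto_scale <- function(m) {
  if (anyNA(m)) stop("input error: missing values not allowed")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) stop("input error: constant rows must be removed first")
  (m - rowMeans(m)) / sqrt(sds)
}

#' PLS discriminant analysis via NIPALS
#'
#' Two-block PLS of the metabolite matrix against a one-hot class matrix,
#' with deflation after each component. VIP scores summarise each
#' metabolite's contribution across components, normalised so the mean
#' squared VIP is 1; classification accuracy is estimated by stratified
#' k-fold cross-validation.
#'
#' @param m Scaled matrix, metabolites x samples (rows are the predictor
#'   variables).
#' @param labels Per-sample class labels (>= 2 classes, each >= 3 samples).
#' @param n_components Number of latent components (truncated to the matrix
#'   rank with a warning if too large).
#' @param cv_folds Folds for stratified cross-validation (set 0 to skip).
#' @param seed Seed for the CV fold assignment.
#' @return Object of class `plsda_model`: `weights` (W), `scores` (T),
#'   `x_loadings` (P), `y_loadings` (Q), `ss_y` (per-component explained Y
#'   sum of squares), `vip`, `cv_accuracy`, `n_components`.
#' @export
fit_plsda <- function(m, labels, n_components = 2, cv_folds = 5, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("input error: need >= 2 classes")
  if (any(table(labels) < 3)) stop("input error: every class needs >= 3 samples")
  X <- t(m)                                   # samples x variables
  Y <- stats::model.matrix(~ 0 + labels)
  core <- .pls2_nipals(scale(X, scale = FALSE),
                       scale(Y, scale = FALSE), n_components)
  vip <- .vip_scores(core)
  cv_acc <- if (cv_folds >= 2)
    .plsda_cv(m, labels, core$A, cv_folds, seed) else NA_real_
  structure(list(weights = core$W, scores = core$T, x_loadings = core$P,
                 y_loadings = core$Q, ss_y = core$ssy, vip = vip,
                 cv_accuracy = cv_acc, n_components = core$A,
                 labels = labels),
            class = "plsda_model")
}

# NIPALS PLS2 on centred X (n x p) and Y (n x q); regression-mode deflation.
.pls2_nipals <- function(X, Y, A, tol = 1e-10, max_iter = 500) {
  p <- ncol(X)
  rank_max <- qr(X)$rank
  if (A > rank_max) {
    warning("n_components truncated to rank ", rank_max)
    A <- rank_max
  }
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, ncol(Y), A); Tm <- matrix(0, nrow(X), A)
  ssy <- numeric(A)
  extracted <- 0
  for (a in seq_len(A)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    w <- rep(0, p)
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- crossprod(X, u)[, 1]
      nw <- sqrt(sum(w_new^2))
      if (!is.finite(nw) || nw < 1e-12) { degenerate <- TRUE; break }
      w_new <- w_new / nw
      tt <- X %*% w_new
      q <- crossprod(Y, tt)[, 1] / sum(tt^2)
      u <- Y %*% q / sum(q^2)
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
      w <- w_new
    }
    if (degenerate) break   # no covariance left between the blocks
    extracted <- a
    tt <- X %*% w
    q <- crossprod(Y, tt)[, 1] / sum(tt^2)
    pp <- crossprod(X, tt)[, 1] / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(q^2)     # explained Y sum of squares
    X <- X - tt %*% t(pp)
    Y <- Y - tt %*% t(q)
  }
  A <- max(extracted, 1L)
  keep <- seq_len(A)
  rn <- colnames(X)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
  rownames(W) <- rownames(P) <- rn
  list(W = W, P = P, Q = Q, T = Tm, ssy = ssy[keep], A = A)
}

# VIP_j = sqrt(p * sum_a SS_a (w_ja/||w_a||)^2 / sum_a SS_a)
.vip_scores <- function(core) {
  p <- nrow(core$W)
  wn <- sweep(core$W, 2, sqrt(colSums(core$W^2)), "/")
  num <- (wn^2) %*% core$ssy
  vip <- sqrt(p * num[, 1] / sum(core$ssy))
  names(vip) <- rownames(core$W)
  vip
}

# stratified k-fold CV accuracy of PLS-DA class prediction
.plsda_cv <- function(m, labels, A, folds, seed) {
  set.seed(seed)
  n <- length(labels)
  fold <- integer(n)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  correct <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    if (!any(te)) next
    Xtr <- t(m[, tr, drop = FALSE]); Xte <- t(m[, te, drop = FALSE])
    Ytr <- stats::model.matrix(~ 0 + droplevels(labels[tr]))
    mx <- colMeans(Xtr); my <- colMeans(Ytr)
    core <- .pls2_nipals(sweep(Xtr, 2, mx), sweep(Ytr, 2, my),
                         min(A, qr(sweep(Xtr, 2, mx))$rank))
    # regression coefficients B = W (P'W)^-1 Q'
    B <- core$W %*% solve(crossprod(core$P, core$W), t(core$Q))
    pred <- sweep(Xte, 2, mx) %*% B
    pred <- sweep(pred, 2, my, "+")
    lev <- levels(droplevels(labels[tr]))
    correct <- correct + sum(lev[max.col(pred, ties.method = "first")] ==
                               as.character(labels[te]))
  }
  correct / n
}

#' Pairwise metabolite group contrasts
#'
#' Per metabolite: equal-variance two-sample t on log intensities, fold
#' change as the ratio of group geometric means with the higher-BMI group in
#' the numerator, and a VIP score from a two-group PLS-DA fitted on the
#' Pareto-scaled pair subset. A metabolite is flagged differential when
#' `VIP > 1` and `p < 0.05`.
#'
#' @param m_log Log2 matrix from [preprocess_metabolites()].
#' @param raw Positive raw intensity matrix (same rows; used for geometric
#'   means; imputed like the log matrix).
#' @param groups Per-sample group factor.
#' @param pair Character length-2: `c(lower_bmi_group, higher_bmi_group)`;
#'   positive log2 fold change then means higher expression in the
#'   higher-BMI group.
#' @param n_components,cv_folds,seed Passed to [fit_plsda()].
#' @return data.frame: `metabolite`, `comparison`, `vip`, `t`, `p`,
#'   `fold_change`, `log2_fc`, `differential`.
#' @export
contrast_metabolites <- function(m_log, raw = NULL, groups, pair,
                                 n_components = 2, cv_folds = 0, seed = 1L) {
  groups <- as.character(groups)
  if (!all(pair %in% groups))
    stop("input error: group(s) absent from data: ",
         paste(setdiff(pair, groups), collapse = ", "))
  lo <- groups == pair[1]; hi <- groups == pair[2]
  if (sum(lo) < 3 || sum(hi) < 3)
    stop("input error: both groups need >= 3 samples")
  sub <- m_log[, lo | hi, drop = FALSE]
  lab <- factor(ifelse(groups[lo | hi] == pair[2], pair[2], pair[1]),
                levels = pair)
  sds <- apply(sub, 1, stats::sd)
  vip <- rep(NA_real_, nrow(sub)); names(vip) <- rownames(sub)
  usable <- sds > 0
  if (sum(usable) >= 2) {
    model <- fit_plsda(pareto_scale(sub[usable, , drop = FALSE]), lab,
                       n_components = n_components, cv_folds = cv_folds,
                       seed = seed)
    vip[usable] <- model$vip
  }
  t_stat <- p_val <- l2fc <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    xa <- sub[i, lab == pair[2]]; xb <- sub[i, lab == pair[1]]
    if (stats::sd(c(xa, xb)) == 0) {
      t_stat[i] <- 0; p_val[i] <- 1
    } else {
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      t_stat[i] <- unname(tt$statistic); p_val[i] <- tt$p.value
    }
    if (is.null(raw)) {
      l2fc[i] <- mean(xa) - mean(xb)   # log2 ratio of geometric means
    } else {
      r <- raw[rownames(sub)[i], lo | hi]
      l2fc[i] <- mean(log2(r[lab == pair[2]])) - mean(log2(r[lab == pair[1]]))
    }
  }
  data.frame(metabolite = rownames(sub),
             comparison = paste(pair[2], "vs", pair[1]),
             vip = unname(vip), t = t_stat, p = p_val,
             fold_change = 2^l2fc, log2_fc = l2fc,
             differential = !is.na(vip) & vip > 1 & p_val < 0.05,
             stringsAsFactors = FALSE)
}

#' Log2 of a fold change
#'
#' @param fold_change Positive ratio of group geometric means.
#' @return Base-2 logarithm.
#' @export
log2fc <- function(fold_change) {
  if (any(fold_change <= 0)) stop("input error: fold change must be positive")
  log2(fold_change)
}
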