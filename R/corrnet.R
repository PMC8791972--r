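# Weighted correlation networks on the most group-variable features:
# soft-threshold selection by scale-free fit, topological overlap, average-
# linkage module detection, module eigengenes and their BMI relationships,
# and hypergeometric over-representation of module members in gene sets.

#' Select the most group-variable features
#'
#' Features whose overall moderated F p-value falls below `p_cut`, ordered
#' by p.
#'
#' @param fit A `moderated_fit`.
#' @param p_cut P-value threshold.
#' @return Character vector of feature ids (possibly empty).
#' @export
select_variable_features <- function(fit, p_cut = 0.05) {
  stopifnot(inherits(fit, "moderated_fit"))
  keep <- which(fit$F_p < p_cut)
  names(fit$F_p)[keep][order(fit$F_p[keep])]
}

# correlation matrix across features (rows), dropping constant rows
.feature_cor <- function(m, on_constant = c("warn", "error")) {
  on_constant <- match.arg(on_constant)
  sds <- apply(m, 1, stats::sd)
  bad <- rownames(m)[sds == 0] %||% which(sds == 0)
  if (length(bad) && any(sds == 0)) {
    msg <- paste("constant features:", paste(bad, collapse = ", "))
    if (on_constant == "error") stop("input error: ", msg)
    warning(msg, "; dropped")
    m <- m[sds > 0, , drop = FALSE]
  }
  list(m = m, cor = stats::cor(t(m)))
}

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the adjacency is `|cor|^beta`; connectivity is
#' binned and the signed R^2 of `log10 p(k)` against `log10 k` measures how
#' scale-free the resulting network is. Returns the smallest power reaching
#' `r2_target`, or the argmax if none does.
#'
#' @param m Numeric matrix, features x samples.
#' @param powers Candidate integer powers.
#' @param r2_target Signed R^2 threshold.
#' @param n_bins Number of connectivity bins for the fit (>= 5 used).
#' @return List with `beta`, `scale_free_r2`, and `table` (per-power signed
#'   R^2 and mean connectivity).
#' @export
pick_soft_threshold <- function(m, powers = 1:20, r2_target = 0.8,
                                n_bins = 10) {
  fc <- .feature_cor(m, "warn")
  C <- abs(fc$cor)
  tab <- data.frame(power = powers, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- C^powers[i]; diag(a) <- 0
    k <- rowSums(a)
    tab$mean_k[i] <- mean(k)
    tab$r2[i] <- scale_free_r2(k, n_bins = n_bins)
  }
  hit <- which(tab$r2 >= r2_target)
  beta <- if (length(hit)) powers[hit[1]] else powers[which.max(tab$r2)]
  list(beta = beta, scale_free_r2 = tab$r2[match(beta, powers)], table = tab)
}

#' Signed scale-free fit index of a connectivity vector
#'
#' @param k Connectivity values.
#' @param n_bins Number of equal-width bins.
#' @return Signed R^2: R^2 of the log-log frequency fit, negated when the
#'   slope is positive (a scale-free network has a decreasing degree
#'   distribution).
#' @export
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  kmean <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 2) return(NA_real_)
  lf <- log10(freq[ok] / sum(freq[ok])); lk <- log10(kmean[ok])
  fit <- stats::lm(lf ~ lk)
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Adjacency and topological overlap matrix
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta`; the topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` credits
#' shared neighbours, with unit diagonal.
#'
#' @param m Numeric matrix, features x samples.
#' @param beta Soft-thresholding power (>= 1).
#' @return List with `adjacency` and `tom` (both features x features).
#' @export
adjacency_tom <- function(m, beta) {
  stopifnot(beta >= 1)
  fc <- .feature_cor(m, "error")
  a <- abs(fc$cor)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a) <- dimnames(fc$cor)
  list(adjacency = a, tom = tom)
}

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' The tree over `1 - TOM` is cut at a fixed height; clusters smaller than
#' `min_size` are folded into `"grey"` (unassigned); surviving modules are
#' labelled `module1, module2, ...` by decreasing size.
#'
#' @param tom Topological overlap matrix.
#' @param min_size Minimum module size (>= 2).
#' @param cut_height Dissimilarity cut height in `[0, 1]`.
#' @return Named character vector feature -> module label, with the `hclust`
#'   tree in attribute `tree`.
#' @export
detect_modules <- function(tom, min_size = 10, cut_height = 0.25) {
  if (min_size < 2) stop("configuration error: min_size must be >= 2")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  lab <- rep("grey", length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (j in seq_along(ord)) lab[raw == ord[j]] <- paste0("module", j)
  }
  names(lab) <- rownames(tom)
  attr(lab, "tree") <- tree
  lab
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member submatrix: the unit-norm per-sample score vector,
#' sign-oriented so the mean correlation with member features is
#' nonnegative. Modules left with fewer than 2 usable members are folded
#' into grey.
#'
#' @param m Numeric matrix, features x samples.
#' @param partition Named feature -> module vector from [detect_modules()].
#' @return List of `eigengene_profile` objects: `module`, `eigengene`
#'   (named per-sample, unit norm), `var_explained`, `n_members`.
#' @export
module_eigengene <- function(m, partition) {
  mods <- setdiff(unique(partition), "grey")
  out <- list()
  for (mod in sort(mods)) {
    members <- names(partition)[partition == mod]
    sub <- m[members, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2) next   # folded into grey
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    eig <- sv$v[, 1]
    if (mean(stats::cor(eig, t(sub))) < 0) eig <- -eig
    names(eig) <- colnames(m)
    out[[mod]] <- structure(
      list(module = mod, eigengene = eig,
           var_explained = sv$d[1]^2 / sum(sv$d^2),
           n_members = nrow(sub)),
      class = "eigengene_profile")
  }
  out
}

#' Test module eigengenes against BMI
#'
#' Per module: Pearson correlation of eigengene with BMI (BH q across
#' modules), a two-segment biphasic fit of eigengene on BMI, and a one-way
#' ANOVA across the BMI groups.
#'
#' @param profiles List from [module_eigengene()].
#' @param bmi Per-sample BMI vector.
#' @param groups Per-sample group factor (3 levels expected; ANOVA skipped
#'   with a warning otherwise).
#' @param alpha,min_arm Passed to [fit_two_lines()].
#' @return The profiles augmented with `bmi_corr` (list: r, p, q),
#'   `twolines` and `anova_p`.
#' @export
eigengene_bmi_tests <- function(profiles, bmi, groups, alpha = 0.05,
                                min_arm = 5) {
  if (!length(profiles)) return(profiles)
  groups <- factor(groups)
  do_anova <- nlevels(droplevels(groups)) >= 3
  if (!do_anova) warning("fewer than 3 groups present: ANOVA skipped")
  ps <- numeric(length(profiles))
  for (i in seq_along(profiles)) {
    eig <- profiles[[i]]$eigengene
    ct <- stats::cor.test(eig, bmi)
    profiles[[i]]$bmi_corr <- list(r = unname(ct$estimate), p = ct$p.value,
                                   q = NA_real_)
    ps[i] <- ct$p.value
    profiles[[i]]$twolines <- fit_two_lines(bmi, eig, alpha = alpha,
                                            min_arm = min_arm)
    profiles[[i]]$anova_p <- if (do_anova)
      stats::anova(stats::lm(eig ~ groups))[["Pr(>F)"]][1] else NA_real_
  }
  qs <- bh_adjust(ps)
  for (i in seq_along(profiles)) profiles[[i]]$bmi_corr$q <- qs[i]
  profiles
}

#' Hypergeometric over-representation of module members in gene sets
#'
#' Upper-tail hypergeometric p-value for the overlap between a module and
#' each set (both restricted to the universe), BH-adjusted across the
#' reported sets.
#'
#' @param module_members Character vector of module features (subset of
#'   `universe`).
#' @param universe Character vector of all candidate features.
#' @param sets Named list of character vectors.
#' @param include_zero Report sets with zero overlap (p = 1) instead of
#'   dropping them.
#' @return data.frame: `set_name`, `set_size`, `overlap`, `p`, `q`.
#' @export
overrep_test <- function(module_members, universe, sets,
                         include_zero = FALSE) {
  if (!all(module_members %in% universe))
    stop("input error: module members must be a subset of the universe")
  N <- length(universe); nmod <- length(module_members)
  rows <- list()
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], universe)
    if (!length(s)) next
    k <- length(intersect(module_members, s))
    if (k == 0 && !include_zero) next
    p <- stats::phyper(k - 1, length(s), N - length(s), nmod,
                       lower.tail = FALSE)
    rows[[nm]] <- data.frame(set_name = nm, set_size = length(s),
                             overlap = k, p = p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_name = character(), set_size = integer(),
               overlap = integer(), p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$q <- if (nrow(out)) bh_adjust(out$p) else numeric()
  out
}
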