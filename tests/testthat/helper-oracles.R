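# Shared fixtures (computed once per run) and independent oracle
# implementations used to cross-check the package's fast paths.

.fx_env <- new.env(parent = emptyenv())

# Default synthetic study with its normalized matrix and biphasic scan.
get_fixture <- function() {
  if (is.null(.fx_env$fx)) {
    d <- default_fixture(seed = 1)
    filt <- filter_low_expression(d$counts,
                                  group_sizes = as.integer(table(d$cohort$batch)))
    m <- remove_batch(quantile_normalize(cpm_log_transform(filt$counts)),
                      d$cohort$batch)
    fits <- scan_features(m, d$cohort$bmi)
    .fx_env$fx <- list(data = d, m = m, fits = fits)
  }
  .fx_env$fx
}

# lm-based arm statistics: slope, t, two-sided p for y ~ x.
oracle_arm <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0) return(list(slope = 0, t = 0, p = 1))
  s <- summary(stats::lm(y ~ x))$coefficients
  list(slope = s[2, 1], t = s[2, 3], p = s[2, 4])
}

# admissible splits of sorted data: both arms >= min_arm, strict x separation
oracle_splits <- function(x, min_arm) {
  n <- length(x)
  ks <- seq(min_arm, n - min_arm)
  ks[x[ks] < x[ks + 1]]
}

oracle_crit <- function(x, y, k) {
  a <- oracle_arm(x[1:k], y[1:k])
  b <- oracle_arm(x[(k + 1):length(x)], y[(k + 1):length(x)])
  min(abs(a$t), abs(b$t))
}

# exhaustive-search oracle: best min(|t1|, |t2|) over all admissible splits
oracle_exhaustive <- function(x, y, min_arm = 5) {
  o <- order(x); x <- x[o]; y <- y[o]
  ks <- oracle_splits(x, min_arm)
  crit <- vapply(ks, function(k) oracle_crit(x, y, k), numeric(1))
  list(crit = max(crit), k = ks[which.max(crit)],
       breakpoint = (x[ks[which.max(crit)]] + x[ks[which.max(crit)] + 1]) / 2)
}

# independent reimplementation of the documented hill climb (lm-based)
oracle_robinhood <- function(x, y, min_arm = 5) {
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  ks <- oracle_splits(x, min_arm)
  xc <- x - mean(x)
  co <- stats::coef(stats::lm(y ~ xc + I(xc^2)))
  bp0 <- if (!is.finite(co[3]) || abs(co[3]) < 1e-10 * max(1, stats::var(y)))
    stats::median(range(x)) else mean(x) - co[2] / (2 * co[3])
  k <- ks[which.min(abs(ks - sum(x < bp0)))]
  crit_arms <- function(k) {
    a <- oracle_arm(x[1:k], y[1:k])
    b <- oracle_arm(x[(k + 1):n], y[(k + 1):n])
    list(t1 = a$t, t2 = b$t, crit = min(abs(a$t), abs(b$t)))
  }
  cur <- crit_arms(k)
  repeat {
    dir <- if (abs(cur$t2) > abs(cur$t1)) 1L else
      if (abs(cur$t1) > abs(cur$t2)) -1L else break
    cand <- if (dir == 1L) ks[ks > k] else rev(ks[ks < k])
    if (!length(cand)) break
    nxt <- crit_arms(cand[1])
    if (nxt$crit > cur$crit) { k <- cand[1]; cur <- nxt } else break
  }
  list(crit = cur$crit, k = k, breakpoint = (x[k] + x[k + 1]) / 2)
}

# naive double-loop topological overlap from the defining formula
oracle_tom <- function(m, beta) {
  a <- abs(stats::cor(t(m)))^beta
  diag(a) <- 0
  p <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- sum(a[i, ] * a[, j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# direct BH step-up from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
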