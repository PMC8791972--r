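# Two-segment ("two lines") biphasic regression: an interior breakpoint is
# located from a quadratic pilot fit, two separate OLS lines are fitted on
# either side, and the breakpoint is refined by a Robin Hood hill climb that
# reallocates observations from the stronger arm to the weaker one while the
# weaker arm's |t| improves. A feature is called u- or n-shaped only when the
# two slopes have opposite signs and both are individually significant —
# this two-sided burden of proof is what protects the scan from the false
# positives a plain quadratic-term test is known to produce.

# Fast per-arm simple-regression statistics from prefix sums. Returns slope,
# t and two-sided p for y ~ x on an index range of the (sorted) data.
.arm_stats <- function(n, sx, sy, sxx, sxy, syy) {
  if (n < 3) return(list(slope = NA_real_, t = 0, p = 1))
  sxx_c <- sxx - sx * sx / n
  if (sxx_c <= 1e-12 * max(1, sxx)) return(list(slope = 0, t = 0, p = 1))
  sxy_c <- sxy - sx * sy / n
  syy_c <- syy - sy * sy / n
  slope <- sxy_c / sxx_c
  rss <- max(syy_c - slope * sxy_c, 0)
  df <- n - 2
  if (rss <= 1e-300) {
    tval <- sign(slope) * Inf
    p <- 0
  } else {
    se <- sqrt(rss / df / sxx_c)
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(slope = slope, t = tval, p = p)
}

# Evaluate both arms for a split after observation k of sorted data, using
# precomputed cumulative sums.
.split_stats <- function(k, n, cx, cy, cxx, cxy, cyy) {
  left <- .arm_stats(k, cx[k], cy[k], cxx[k], cxy[k], cyy[k])
  right <- .arm_stats(n - k, cx[n] - cx[k], cy[n] - cy[k],
                      cxx[n] - cxx[k], cxy[n] - cxy[k], cyy[n] - cyy[k])
  list(left = left, right = right, crit = min(abs(left$t), abs(right$t)))
}

#' Fit a two-segment breakpoint regression to one feature
#'
#' @param x Covariate vector (e.g. BMI).
#' @param y Response vector (e.g. log2 expression of one feature).
#' @param alpha Per-arm significance level for the shape call.
#' @param min_arm Minimum observations per arm (breakpoint search is clipped
#'   so both arms keep at least this many points).
#' @param method `"robinhood"` (default): quadratic-extremum start followed
#'   by a one-observation-at-a-time hill climb on `min(|t1|, |t2|)`;
#'   `"exhaustive"`: search every admissible split for the global maximum of
#'   `min(|t1|, |t2|)`.
#' @return A list of class `twolines_fit` with fields `breakpoint` (midpoint
#'   between the two boundary observations), `slope1`, `p1`, `slope2`, `p2`,
#'   `t1`, `t2`, `shape` (`"u"`, `"n"` or `"none"`), `n1`, `n2`. Degenerate
#'   inputs (too few points, constant response) yield `shape = "none"` with
#'   `p1 = p2 = 1` rather than an error, so feature-wise scans never abort.
#' @export
fit_two_lines <- function(x, y, alpha = 0.05, min_arm = 5,
                          method = c("robinhood", "exhaustive")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  degenerate <- structure(
    list(breakpoint = NA_real_, slope1 = NA_real_, p1 = 1,
         slope2 = NA_real_, p2 = 1, t1 = 0, t2 = 0, shape = "none",
         n1 = NA_integer_, n2 = NA_integer_, method = method),
    class = "twolines_fit")
  if (n < 2 * min_arm || length(unique(x)) < 2 * min_arm ||
      stats::sd(y) == 0)
    return(degenerate)
  o <- order(x)
  x <- x[o]; y <- y[o]
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  # admissible splits: both arms >= min_arm and strict separation in x
  ks <- seq(min_arm, n - min_arm)
  ks <- ks[x[ks] < x[ks + 1]]
  if (!length(ks)) return(degenerate)

  if (method == "exhaustive") {
    crit <- vapply(ks, function(k)
      .split_stats(k, n, cx, cy, cxx, cxy, cyy)$crit, numeric(1))
    k <- ks[which.max(crit)]
  } else {
    # quadratic pilot fit: extremum of a + b x + c x^2
    xc <- x - mean(x)
    qfit <- stats::lm.fit(cbind(1, xc, xc * xc), y)
    cc <- qfit$coefficients[3]
    if (!is.finite(cc) || abs(cc) < 1e-10 * max(1, stats::var(y))) {
      bp0 <- stats::median(range(x))
    } else {
      bp0 <- mean(x) - qfit$coefficients[2] / (2 * cc)
    }
    k <- sum(x < bp0)
    k <- ks[which.min(abs(ks - k))]   # clip to nearest admissible split
    cur <- .split_stats(k, n, cx, cy, cxx, cxy, cyy)
    repeat {
      # move the breakpoint toward the arm with the larger |t|, handing one
      # observation to the weaker arm
      dir <- if (abs(cur$right$t) > abs(cur$left$t)) 1L else
        if (abs(cur$left$t) > abs(cur$right$t)) -1L else break
      cand <- if (dir == 1L) ks[ks > k] else rev(ks[ks < k])
      if (!length(cand)) break
      k2 <- cand[1]
      nxt <- .split_stats(k2, n, cx, cy, cxx, cxy, cyy)
      if (nxt$crit > cur$crit) { k <- k2; cur <- nxt } else break
    }
  }
  s <- .split_stats(k, n, cx, cy, cxx, cxy, cyy)
  slope1 <- s$left$slope; slope2 <- s$right$slope
  p1 <- s$left$p; p2 <- s$right$p
  shape <- "none"
  if (is.finite(slope1) && is.finite(slope2) && max(p1, p2) < alpha) {
    if (slope1 < 0 && slope2 > 0) shape <- "u"
    if (slope1 > 0 && slope2 < 0) shape <- "n"
  }
  structure(list(breakpoint = (x[k] + x[k + 1]) / 2,
                 slope1 = slope1, p1 = p1, slope2 = slope2, p2 = p2,
                 t1 = s$left$t, t2 = s$right$t, shape = shape,
                 n1 = k, n2 = n - k, method = method),
            class = "twolines_fit")
}

#' Scan every feature of a matrix for biphasic covariate response
#'
#' Applies [fit_two_lines()] to each row. The BH-adjusted q-value is computed
#' on the combined p-value `max(p1, p2)`, restricted to features whose two
#' slopes have opposite signs (the only candidates for a u/n call);
#' same-sign features get `NA`.
#'
#' @param m Numeric matrix, features x samples.
#' @param x Covariate vector aligned with the columns of `m`.
#' @inheritParams fit_two_lines
#' @return data.frame with one row per feature: `feature_id`, `breakpoint`,
#'   `slope1`, `p1`, `slope2`, `p2`, `shape`, `q_value`.
#' @export
scan_features <- function(m, x, alpha = 0.05, min_arm = 5,
                          method = c("robinhood", "exhaustive")) {
  method <- match.arg(method)
  if (nrow(m) == 0)
    return(data.frame(feature_id = character(), breakpoint = numeric(),
                      slope1 = numeric(), p1 = numeric(), slope2 = numeric(),
                      p2 = numeric(), shape = character(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  if (ncol(m) != length(x))
    stop("input error: columns of m do not align with covariate length")
  fits <- lapply(seq_len(nrow(m)), function(i)
    fit_two_lines(x, m[i, ], alpha = alpha, min_arm = min_arm,
                  method = method))
  out <- data.frame(
    feature_id = rownames(m) %||% sprintf("feature%d", seq_len(nrow(m))),
    breakpoint = vapply(fits, `[[`, numeric(1), "breakpoint"),
    slope1 = vapply(fits, `[[`, numeric(1), "slope1"),
    p1 = vapply(fits, `[[`, numeric(1), "p1"),
    slope2 = vapply(fits, `[[`, numeric(1), "slope2"),
    p2 = vapply(fits, `[[`, numeric(1), "p2"),
    shape = vapply(fits, `[[`, character(1), "shape"),
    stringsAsFactors = FALSE)
  opp <- !is.na(out$slope1) & !is.na(out$slope2) &
    sign(out$slope1) != sign(out$slope2)
  out$q_value <- NA_real_
  if (any(opp))
    out$q_value[opp] <- bh_adjust(pmax(out$p1[opp], out$p2[opp]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize significant breakpoints into integer covariate bins
#'
#' Breakpoints of features called u- or n-shaped are rounded to the nearest
#' integer; the modal region is the argmax bin together with every bin whose
#' count is at least 80% of the maximum and contiguous with it.
#'
#' @param fits data.frame from [scan_features()].
#' @return List of class `breakpoint_summary` with `bins`, `counts`,
#'   `modal_bins`. With no significant fits the summary is empty and a
#'   warning is raised.
#' @export
summarize_breakpoints <- function(fits) {
  sig <- fits[fits$shape != "none" & is.finite(fits$breakpoint), ,
              drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no significant biphasic fits: empty breakpoint summary")
    return(structure(list(bins = integer(), counts = integer(),
                          modal_bins = integer()),
                     class = "breakpoint_summary"))
  }
  b <- round(sig$breakpoint)
  tab <- table(b)
  bins <- as.integer(names(tab))
  counts <- as.integer(tab)
  top <- bins[which.max(counts)]
  eligible <- bins[counts >= 0.8 * max(counts)]
  # keep only the bins contiguous (through other eligible bins) with argmax
  modal <- top
  repeat {
    grown <- unique(c(modal, modal - 1L, modal + 1L))
    grown <- intersect(grown, eligible)
    if (length(grown) == length(modal)) break
    modal <- grown
  }
  structure(list(bins = bins, counts = counts,
                 modal_bins = sort(as.integer(modal))),
            class = "breakpoint_summary")
}

#' Derive covariate group boundaries from the breakpoint mode
#'
#' The middle group spans the modal breakpoint bins plus/minus `halfwidth`
#' BMI units; samples below are "low", above are "high".
#'
#' @param summary A `breakpoint_summary`.
#' @param halfwidth Half-width in BMI units added on each side of the modal
#'   bins.
#' @return List of class `group_scheme` with `lower`, `upper`, `labels`.
#' @export
define_groups <- function(summary, halfwidth = 3) {
  if (!length(summary$modal_bins))
    stop("configuration error: empty breakpoint summary")
  lower <- min(summary$modal_bins) - halfwidth
  upper <- max(summary$modal_bins) + halfwidth
  if (!(lower < upper))
    stop("configuration error: degenerate group scheme (lower >= upper)")
  structure(list(lower = lower, upper = upper,
                 labels = c("low", "mid", "high")),
            class = "group_scheme")
}

#' Assign samples to BMI groups
#'
#' `low` iff `bmi < lower`; `mid` iff `lower <= bmi <= upper` (both bounds
#' inclusive); `high` iff `bmi > upper`.
#'
#' @param bmi Numeric vector of BMI values.
#' @param scheme A `group_scheme`.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
assign_group <- function(bmi, scheme) {
  stopifnot(inherits(scheme, "group_scheme"), all(is.finite(bmi)))
  lab <- ifelse(bmi < scheme$lower, "low",
                ifelse(bmi <= scheme$upper, "mid", "high"))
  factor(lab, levels = scheme$labels)
}
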