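make_null_data <- function(G = 200, n = 18, seed = 1, d0 = 4, s0 = 0.5) {
  set.seed(seed)
  v <- s0^2 * d0 / rchisq(G, d0)
  m <- matrix(rnorm(G * n, 0, rep(sqrt(v), n)), G, n,
              dimnames = list(sprintf("g%04d", seq_len(G)), NULL))
  groups <- factor(rep(c("low", "mid", "high"), length.out = n),
                   levels = c("low", "mid", "high"))
  list(m = m, groups = groups, v = v)
}

test_that("d0 overrides reduce to ordinary t and to full shrinkage", {
  d <- make_null_data(seed = 2)
  f0 <- fit_moderated_model(d$m, d$groups, d0_override = 0)
  # ordinary t per feature for the mid-low contrast, via lm
  X <- stats::model.matrix(~ 0 + d$groups)
  cvec <- c(-1, 1, 0)   # mid - low on (low, mid, high) means
  V <- chol2inv(chol(crossprod(X)))
  for (i in c(1, 7, 42)) {
    fit_lm <- stats::lm(d$m[i, ] ~ 0 + d$groups)
    est <- sum(cvec * stats::coef(fit_lm))
    se <- summary(fit_lm)$sigma * sqrt(drop(t(cvec) %*% V %*% cvec))
    expect_equal(unname(f0$t[i, "mid-low"]), est / se, tolerance = 1e-10)
  }
  expect_equal(f0$s2_post, f0$s2, tolerance = 1e-12)

  fI <- fit_moderated_model(d$m, d$groups, d0_override = Inf)
  expect_true(all(abs(fI$s2_post - fI$s02) < 1e-12))
})

test_that("posterior variances shrink monotonically toward the prior", {
  d <- make_null_data(seed = 3)
  fit <- fit_moderated_model(d$m, d$groups)
  expect_gt(fit$d0, 0)
  lo <- pmin(fit$s2, fit$s02); hi <- pmax(fit$s2, fit$s02)
  expect_true(all(fit$s2_post >= lo - 1e-12 & fit$s2_post <= hi + 1e-12))
  # larger d0 pulls the posterior strictly closer to s0^2
  post2 <- (2 * fit$d0 * fit$s02 + fit$df_resid * fit$s2) /
    (2 * fit$d0 + fit$df_resid)
  expect_true(all(abs(post2 - fit$s02) <= abs(fit$s2_post - fit$s02) + 1e-12))
})

test_that("variance moment matching agrees with the established EB reference", {
  d <- make_null_data(G = 500, seed = 4)
  fit <- fit_moderated_model(d$m, d$groups)
  sq <- limma::squeezeVar(fit$s2, df = fit$df_resid)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(fit$s02, sq$var.prior, tolerance = 1e-8)
  expect_equal(fit$s2_post, sq$var.post, tolerance = 1e-10)
  # and the hyperparameter estimate is in the right range
  expect_gt(fit$d0, 2); expect_lt(fit$d0, 8)   # truth d0 = 4, factor-2 band
})

test_that("null simulations give calibrated moderated tests", {
  d <- make_null_data(G = 1000, n = 20, seed = 5)
  fit <- fit_moderated_model(d$m, d$groups)
  rej <- mean(fit$p < 0.05)
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
  rejF <- mean(fit$F_p < 0.05)
  expect_gte(rejF, 0.03); expect_lte(rejF, 0.07)
})

test_that("rank-deficient designs fail loudly with the aliased columns named", {
  d <- make_null_data(seed = 6)
  expect_error(fit_moderated_model(d$m, d$groups, batch = d$groups),
               "design error")
  expect_error(fit_moderated_model(d$m[, 1:4], factor(c("a", "a", "b", "b")),
                                   d0_override = NULL),
               NA)
  expect_error(fit_moderated_model(d$m[, 1:3], factor(c("a", "a", "b"))),
               "design error")
})

test_that("camera reduces to the plain two-sample t when correlation is absent", {
  set.seed(7)
  G <- 60
  stat <- rnorm(G); names(stat) <- sprintf("g%02d", 1:G)
  # uncorrelated residuals: rho estimate ~ 0, floor keeps VIF near 1
  resid <- matrix(rnorm(G * 20), G, 20, dimnames = list(names(stat), NULL))
  out <- camera_test(stat, resid, list(S = names(stat)[1:10]))
  tt <- stats::t.test(stat[1:10], stat[-(1:10)], var.equal = TRUE)
  # VIF close to 1 -> T close to the pooled two-sample t
  expect_equal(out$t, unname(tt$statistic), tolerance = 0.35)
  # equal member and non-member statistics give T = 0, p = 1
  eq <- stats::setNames(rep(1, G), names(stat))
  eq_out <- camera_test(eq, resid, list(S = names(stat)[1:10]))
  expect_equal(eq_out$t, 0)
  expect_equal(eq_out$p, 1)
})

test_that("camera matches the reference implementation on identical input", {
  set.seed(8)
  n <- 20; G <- 100
  grp <- factor(rep(c("A", "B"), each = 10))
  X <- matrix(rnorm(G * n), G, n, dimnames = list(sprintf("g%03d", 1:G), NULL))
  lat <- rnorm(n)
  X[1:10, ] <- sqrt(0.25) * matrix(lat, 10, n, byrow = TRUE) +
    sqrt(0.75) * X[1:10, ]
  X[1:10, grp == "B"] <- X[1:10, grp == "B"] + 0.8
  fit <- fit_moderated_model(X, grp)
  mine <- camera_test(fit$t[, 1], fit$residuals, list(S = rownames(X)[1:10]),
                      df_stat = fit$df_resid)
  ref <- limma::camera(X, index = list(S = 1:10),
                       design = stats::model.matrix(~grp),
                       inter.gene.cor = NA)
  expect_equal(mine$mean_corr, ref$Correlation, tolerance = 1e-8)
  # reference converts its own (unmoderated) t to z; deep-tail p-values agree
  # to a modest factor, not exactly
  expect_lt(abs(log(mine$p / ref$PValue)), 0.7)
})

test_that("camera rejects degenerate sets and records skipped ones", {
  set.seed(9)
  stat <- stats::setNames(rnorm(20), sprintf("g%02d", 1:20))
  resid <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(names(stat), NULL))
  expect_error(camera_test(stat, resid, list(All = names(stat))),
               "every gene")
  expect_warning(out <- camera_test(stat, resid,
                                    list(Tiny = "g01", Ok = c("g01", "g02"))),
                 "skipped")
  expect_equal(attr(out, "skipped"), "Tiny")
  expect_equal(out$set_name, "Ok")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1.0), 1.0)
  set.seed(10)
  p <- runif(50)^2
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "input error")
})
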