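test_that("metabolite preprocessing applies the missingness, RSD and imputation rules", {
  set.seed(1)
  n <- 54
  panel <- matrix(rlnorm(5 * n, 10, 0.5), 5, n,
                  dimnames = list(c("drop22", "keep", "const", "wild", "half"),
                                  sprintf("s%02d", 1:n)))
  panel["drop22", 1:12] <- NA                  # 12/54 = 22% missing
  panel["const", ] <- 7
  panel["wild", ] <- c(rep(1e-3, n - 1), 1e6)  # RSD far above 3
  panel["half", 1] <- NA
  panel["half", 2:n] <- 4:(n + 2)
  out <- preprocess_metabolites(panel)
  expect_false("drop22" %in% rownames(out))
  expect_false("const" %in% rownames(out))
  expect_false("wild" %in% rownames(out))
  expect_false(anyNA(out))
  expect_equal(out["half", 1], log2(4 / 2))    # half of the observed minimum
  rec <- attr(out, "record")
  expect_equal(rec$dropped_missing, "drop22")
  expect_error(preprocess_metabolites(matrix(-1, 1, 3)), "positive")
})

test_that("Pareto scaling has the closed form and the variance identity", {
  m <- matrix(c(0, 2, 4), 1, 3, dimnames = list("r", NULL))
  ps <- pareto_scale(m)
  expect_equal(unname(ps[1, ]), c(-sqrt(2), 0, sqrt(2)))
  set.seed(2)
  r <- matrix(rnorm(60, 5, 2), 4, 15)
  pr <- pareto_scale(r)
  expect_equal(apply(pr, 1, stats::var), apply(r, 1, stats::sd),
               tolerance = 1e-10)
  expect_equal(unname(rowMeans(pr)), rep(0, 4), tolerance = 1e-12)
  expect_error(pareto_scale(rbind(r, 0)), "constant")
})

test_that("PLS-DA satisfies the VIP identity and concentrates weight on a separator", {
  set.seed(3)
  p <- 25; n <- 30
  lab <- factor(rep(c("A", "B"), each = 15))
  m <- matrix(rnorm(p * n), p, n, dimnames = list(sprintf("v%02d", 1:p),
                                                  sprintf("s%02d", 1:n)))
  m[1, ] <- ifelse(lab == "A", -2, 2) + rnorm(n, 0, 0.05)
  model <- fit_plsda(pareto_scale(m), lab, n_components = 1, cv_folds = 3)
  expect_equal(mean(model$vip^2), 1, tolerance = 1e-8)
  expect_equal(which.max(model$vip), 1L, ignore_attr = TRUE)
  expect_equal(unname(model$vip[1]), sqrt(p), tolerance = 0.4)
  expect_gt(model$cv_accuracy, 0.9)

  m2 <- fit_plsda(pareto_scale(m), lab, n_components = 3, cv_folds = 0)
  expect_equal(mean(m2$vip^2), 1, tolerance = 1e-8)
  # successive scores orthogonal
  g <- crossprod(m2$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("PLS-DA VIP agrees with the reference multivariate implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  p <- 18; n <- 26
  lab <- factor(rep(c("A", "B"), each = 13))
  m <- matrix(rnorm(p * n), p, n, dimnames = list(sprintf("v%02d", 1:p),
                                                  sprintf("s%02d", 1:n)))
  m[2, lab == "B"] <- m[2, lab == "B"] + 1.5
  ps <- pareto_scale(m)
  mine <- fit_plsda(ps, lab, n_components = 2, cv_folds = 0)
  ref <- mixOmics::vip(mixOmics::plsda(t(ps), lab, ncomp = 2, scale = FALSE))
  expect_equal(unname(mine$vip), unname(ref[, 2]), tolerance = 1e-6)
})

test_that("all-noise PLS-DA classifies at chance level", {
  set.seed(5)
  lab <- factor(rep(c("A", "B"), each = 20))
  m <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(sprintf("v%02d", 1:30), sprintf("s%02d", 1:40)))
  acc <- fit_plsda(pareto_scale(m), lab, n_components = 2, cv_folds = 5,
                   seed = 5)$cv_accuracy
  # binomial band around 0.5 at n = 40 (99.9%)
  expect_true(abs(acc - 0.5) < 3.3 * sqrt(0.25 / 40) + 0.1)
})

test_that("metabolite contrasts combine VIP, t and geometric-mean fold change", {
  set.seed(6)
  n <- 30
  groups <- rep(c("low", "mid"), each = 15)
  raw <- matrix(rlnorm(10 * n, 10, 0.4), 10, n,
                dimnames = list(sprintf("m%02d", 1:10), sprintf("s%02d", 1:n)))
  raw[1, groups == "mid"] <- raw[1, groups == "mid"] * 2^1.2
  ml <- log2(raw)
  out <- contrast_metabolites(ml, raw, groups, pair = c("low", "mid"))
  expect_equal(out$log2_fc, log2(out$fold_change), tolerance = 1e-6)
  expect_true(out$differential[1])
  expect_equal(out$log2_fc[1], 1.2, tolerance = 0.45)
  # antisymmetry under direction swap
  rev_out <- contrast_metabolites(ml, raw, groups, pair = c("mid", "low"))
  expect_equal(rev_out$log2_fc, -out$log2_fc, tolerance = 1e-10)
  expect_equal(rev_out$fold_change, 1 / out$fold_change, tolerance = 1e-10)
  # identical groups: no signal
  same <- cbind(raw[, 1:15], raw[, 1:15])
  colnames(same) <- sprintf("s%02d", 1:30)
  out0 <- contrast_metabolites(log2(same), same, groups, c("low", "mid"))
  expect_true(all(abs(out0$t) < 1e-8))
  expect_true(all(out0$fold_change == 1))
  expect_false(any(out0$differential))
  expect_error(contrast_metabolites(ml, raw, groups, c("low", "high")),
               "absent")
})

test_that("t-tests on log intensities ignore global multiplicative scaling", {
  set.seed(7)
  groups <- rep(c("low", "mid"), each = 10)
  raw <- matrix(rlnorm(5 * 20, 8, 0.5), 5, 20,
                dimnames = list(sprintf("m%02d", 1:5), sprintf("s%02d", 1:20)))
  a <- contrast_metabolites(log2(raw), raw, groups, c("low", "mid"))
  b <- contrast_metabolites(log2(raw * 1000), raw * 1000, groups,
                            c("low", "mid"))
  expect_equal(a$t, b$t, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("log2 fold changes reproduce the printed metabolite table values", {
  expect_equal(log2fc(1.0), 0.0)
  expect_equal(log2fc(1.788), 0.838, tolerance = 5e-4)
  expect_equal(log2fc(0.687), -0.541, tolerance = 2e-3)
  expect_error(log2fc(0), "input error")
  expect_error(log2fc(-2), "input error")
})
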