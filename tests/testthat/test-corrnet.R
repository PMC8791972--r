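# three correlated feature blocks plus noise features, used across tests
make_blocks <- function(seed = 1, per_block = 20, n = 40, rho = 0.8,
                        n_noise = 0) {
  set.seed(seed)
  blocks <- 3
  m <- matrix(0, blocks * per_block + n_noise, n)
  truth <- integer(nrow(m))
  for (b in seq_len(blocks)) {
    lat <- rnorm(n)
    idx <- (b - 1) * per_block + seq_len(per_block)
    m[idx, ] <- sqrt(rho) * matrix(lat, per_block, n, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(per_block * n), per_block, n)
    truth[idx] <- b
  }
  if (n_noise > 0)
    m[blocks * per_block + seq_len(n_noise), ] <- rnorm(n_noise * n)
  rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
  list(m = m, truth = truth)
}

test_that("variable-feature selection follows the overall F p-value", {
  set.seed(2)
  n <- 24
  groups <- factor(rep(c("low", "mid", "high"), each = 8),
                   levels = c("low", "mid", "high"))
  m <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  m[1:30, groups == "high"] <- m[1:30, groups == "high"] + 3
  fit <- fit_moderated_model(m, groups)
  sel <- select_variable_features(fit, p_cut = 0.05)
  expect_true(all(sprintf("g%03d", 1:30) %in% sel))
  expect_equal(length(select_variable_features(fit, p_cut = 1)), 200)
  expect_length(select_variable_features(fit, p_cut = 0), 0)
  # ordered by p
  expect_equal(sel, sel[order(fit$F_p[sel])])
})

test_that("TOM matches the defining formula and stays within bounds", {
  bl <- make_blocks(seed = 3, per_block = 4, n = 30, n_noise = 2)
  at <- adjacency_tom(bl$m, beta = 6)
  expect_equal(at$tom, oracle_tom(bl$m, 6), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(at$tom >= 0 & at$tom <= 1 + 1e-12))
  expect_equal(unname(diag(at$tom)), rep(1, nrow(bl$m)))
  expect_equal(at$tom, t(at$tom))
  # three identical features: a clique with TOM exactly 1
  cl <- matrix(rnorm(20), 1, 20)[rep(1, 3), ] + 0
  cl <- cl + matrix(rnorm(60, 0, 1e-8), 3, 20)
  rownames(cl) <- c("a", "b", "c")
  expect_equal(unname(adjacency_tom(cl, 1)$tom), matrix(1, 3, 3),
               tolerance = 1e-6)
  const <- rbind(x = rep(1, 10), y = rnorm(10))
  expect_error(adjacency_tom(const, 2), "constant features")
})

test_that("soft-threshold choice reproduces an independent per-power table", {
  bl <- make_blocks(seed = 4, per_block = 10, n = 30, n_noise = 10)
  st <- pick_soft_threshold(bl$m, powers = c(1, 2, 4, 6, 8), r2_target = 0.8)
  # independent recomputation per power
  C <- abs(stats::cor(t(bl$m)))
  for (i in seq_along(st$table$power)) {
    a <- C^st$table$power[i]; diag(a) <- 0
    k <- rowSums(a)
    expect_equal(st$table$mean_k[i], mean(k), tolerance = 1e-12)
    expect_equal(st$table$r2[i], scale_free_r2(k), tolerance = 1e-12)
  }
  hit <- which(st$table$r2 >= 0.8)
  expected_beta <- if (length(hit)) st$table$power[hit[1]] else
    st$table$power[which.max(st$table$r2)]
  expect_equal(st$beta, expected_beta)
  # a zero target is met by the first power whose signed fit is nonnegative
  st0 <- pick_soft_threshold(bl$m, powers = c(2, 5, 9), r2_target = 0)
  expect_equal(st0$beta, st0$table$power[which(st0$table$r2 >= 0)[1]])
})

test_that("planted correlation blocks are recovered as modules", {
  skip_if_not_installed("mclust")
  bl <- make_blocks(seed = 5)
  at <- adjacency_tom(bl$m, beta = 2)
  part <- detect_modules(at$tom, min_size = 10, cut_height = 0.6)
  got <- as.integer(factor(part))
  ari <- mclust::adjustedRandIndex(got, bl$truth)
  expect_gte(ari, 0.8)
  # extreme cut heights collapse or dissolve the partition
  expect_true(all(detect_modules(at$tom, 10, 0) == "grey"))
  expect_equal(length(unique(detect_modules(at$tom, 2, 1))), 1)
  expect_error(detect_modules(at$tom, min_size = 1), "configuration error")
})

test_that("module labels are stable under feature permutation", {
  bl <- make_blocks(seed = 6, per_block = 12, n = 30)
  at <- adjacency_tom(bl$m, 6)
  p1 <- detect_modules(at$tom, 5, 0.6)
  perm <- sample(nrow(bl$m))
  at2 <- adjacency_tom(bl$m[perm, ], 6)
  p2 <- detect_modules(at2$tom, 5, 0.6)
  # same induced partition: co-membership matrices agree
  co1 <- outer(p1, p1, "==")
  co2 <- outer(p2[rownames(bl$m)], p2[rownames(bl$m)], "==")
  expect_equal(unname(co1), unname(co2))
})

test_that("eigengenes equal the first right singular vector up to sign", {
  bl <- make_blocks(seed = 7, per_block = 8, n = 25)
  part <- stats::setNames(rep(c("module1", "module2", "module3"), each = 8),
                          rownames(bl$m))
  profs <- module_eigengene(bl$m, part)
  expect_length(profs, 3)
  for (p in profs) {
    members <- names(part)[part == p$module]
    z <- t(scale(t(bl$m[members, ])))
    sv <- svd(z)
    ref <- sv$v[, 1]
    if (sum(ref * p$eigengene) < 0) ref <- -ref
    expect_equal(unname(p$eigengene), ref, tolerance = 1e-8)
    expect_equal(sum(p$eigengene^2), 1, tolerance = 1e-10)
    expect_equal(p$var_explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
    expect_gte(mean(stats::cor(p$eigengene, t(bl$m[members, ]))), 0)
  }
  # flipping all member features does not flip the oriented eigengene meaning
  flipped <- module_eigengene(-bl$m, part)
  for (i in seq_along(profs))
    expect_gte(mean(stats::cor(flipped[[i]]$eigengene,
                               t(-bl$m[part == flipped[[i]]$module, ]))), 0)
  # a module of two identical features explains all its variance
  two <- bl$m[1:2, ]; two[2, ] <- two[1, ]
  rownames(two) <- c("a", "b")
  pr <- module_eigengene(two, c(a = "module1", b = "module1"))
  expect_equal(pr[[1]]$var_explained, 1, tolerance = 1e-10)
})

test_that("eigengene-BMI tests identify linear and vee relationships", {
  set.seed(8)
  bmi <- runif(40, 18, 45)
  base <- matrix(rnorm(4 * 40, sd = 0.05), 4, 40)
  m <- rbind(bmi + base[1, ], bmi + base[2, ],
             abs(bmi - 28) + base[3, ], abs(bmi - 28) + base[4, ])
  rownames(m) <- c("l1", "l2", "v1", "v2")
  part <- stats::setNames(c("module1", "module1", "module2", "module2"),
                          rownames(m))
  profs <- module_eigengene(m, part)
  groups <- assign_group(bmi, structure(list(lower = 25, upper = 32,
                                             labels = c("low", "mid", "high")),
                                        class = "group_scheme"))
  out <- eigengene_bmi_tests(profs, bmi, groups)
  lin <- out[[which(vapply(out, `[[`, character(1), "module") == "module1")]]
  vee <- out[[which(vapply(out, `[[`, character(1), "module") == "module2")]]
  expect_gt(abs(lin$bmi_corr$r), 0.99)
  expect_equal(lin$twolines$shape, "none")
  expect_equal(vee$twolines$shape, "u")
  expect_lt(abs(vee$twolines$breakpoint - 28), 1.5)
  expect_lt(vee$anova_p, 0.05)
  expect_warning(eigengene_bmi_tests(profs, bmi,
                                     factor(rep("mid", 40))), "ANOVA skipped")
})

test_that("over-representation p-values are hypergeometric", {
  universe <- sprintf("u%02d", 1:10)
  sets <- list(S = universe[1:5])
  out <- overrep_test(universe[1:5], universe, sets)
  expect_equal(out$p, 1 / choose(10, 5), tolerance = 1e-12)
  # zero overlap dropped by default, reported with the flag
  out0 <- overrep_test(universe[6:10], universe, sets)
  expect_equal(nrow(out0), 0)
  outz <- overrep_test(universe[6:10], universe, sets, include_zero = TRUE)
  expect_equal(outz$p, 1)
  expect_error(overrep_test(c("zz"), universe, sets), "subset")
  # Monte-Carlo agreement of the upper-tail probability
  set.seed(9)
  N <- 30; K <- 8; nmod <- 10
  uni <- sprintf("x%02d", 1:N)
  draws <- replicate(4000, length(intersect(sample(uni, nmod), uni[1:K])))
  k_obs <- 4
  emp <- mean(draws >= k_obs)
  expect_equal(stats::phyper(k_obs - 1, K, N - K, nmod, lower.tail = FALSE),
               emp, tolerance = 4 * sqrt(emp * (1 - emp) / 4000))
})
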