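test_that("NIPALS PCA agrees with the singular value decomposition", {
  set.seed(31)
  X <- matrix(rnorm(24), 6, 4)
  m <- fit_pca(X, 3)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  for (a in 1:3) {
    ta <- sv$u[, a] * sv$d[a]
    expect_lt(min(sum((m$scores[, a] - ta)^2), sum((m$scores[, a] + ta)^2)),
              1e-8 * sum(ta^2))
    expect_equal(m$r2x[a], sv$d[a]^2 / sum(sv$d^2), tolerance = 1e-8)
  }
})

test_that("PCA captures exact low-rank structure", {
  set.seed(32)
  X <- tcrossprod(rnorm(8), rnorm(5))           # rank 1 after centering? no:
  X <- sweep(X, 2, colMeans(X))                 # still rank 1
  m <- fit_pca(X, 1, center = FALSE)
  expect_equal(m$r2x[1], 1, tolerance = 1e-10)
  # reconstruction improves monotonically with more components
  set.seed(33)
  Y <- matrix(rnorm(60), 10, 6)
  errs <- vapply(1:4, function(a) {
    f <- fit_pca(Y, a)
    Yc <- sweep(Y, 2, colMeans(Y))
    sum((Yc - tcrossprod(f$scores, f$loadings))^2)
  }, 0)
  expect_true(all(diff(errs) < 1e-10))
})

test_that("Hotelling T2 flags a constructed extreme sample", {
  set.seed(34)
  X <- matrix(rnorm(20 * 5, sd = 0.05), 20, 5)
  X[7, ] <- X[7, ] + 5
  rownames(X) <- sprintf("s%02d", 1:20)
  hot <- hotelling_outliers(fit_pca(X, 2))
  expect_identical(hot$flagged, "s07")
})

test_that("one-component Hotelling threshold matches the closed form", {
  set.seed(35)
  X <- matrix(rnorm(15 * 4), 15, 4)
  hot <- hotelling_outliers(fit_pca(X, 1), alpha = 0.05)
  N <- 15
  expect_equal(hot$threshold,
               (N^2 - 1) / (N * (N - 1)) * qf(0.95, 1, N - 1))
  # with one component, T2 is the squared standardized score
  m <- fit_pca(X, 1)
  expect_equal(unname(hot$t2), drop(m$scores^2) / var(drop(m$scores)),
               tolerance = 1e-12)
})

test_that("PLS-DA matches an independent NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(36)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  m <- fit_pls_da(X, y, n_components = 2)
  or <- mixOmics::pls(X, y, ncomp = 2, scale = FALSE, mode = "regression")
  for (a in 1:2) {
    ta <- or$variates$X[, a]
    expect_lt(min(sum((m$scores[, a] - ta)^2), sum((m$scores[, a] + ta)^2)),
              1e-8)
  }
  pred <- predict(m, X)
  orp <- predict(or, X)$predict[, 1, 2]
  expect_equal(drop(pred), unname(orp), tolerance = 1e-8)
})

test_that("duplicated response columns leave PLS scores unchanged", {
  set.seed(37)
  X <- matrix(rnorm(60), 12, 5)
  y <- rep(0:1, each = 6)
  m1 <- fit_pls_da(X, y, n_components = 2)
  m2 <- fit_pls_da(X, cbind(y, y), n_components = 2)
  expect_equal(m1$scores, m2$scores, tolerance = 1e-8)
})

test_that("separable clusters separate in the first PLS component", {
  set.seed(38)
  X <- rbind(matrix(rnorm(30, 0, 0.1), 6), matrix(rnorm(30, 3, 0.1), 6))
  y <- rep(0:1, each = 6)
  m <- fit_pls_da(X, y, n_components = 1)
  t1 <- m$scores[, 1]
  expect_true(max(t1[y == 0]) < min(t1[y == 1]) ||
              min(t1[y == 0]) > max(t1[y == 1]))
  expect_error(fit_pls_da(X, rep(1, 12), n_components = 1), "degenerate")
})

test_that("latent model invariants hold: orthogonal scores, bounded R2", {
  set.seed(39)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rep(0:1, each = 10)
  m <- fit_pls_da(X, y, n_components = 3)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  expect_true(all(m$r2x >= 0 & m$r2x <= 1))
  expect_true(all(m$r2y >= 0 & m$r2y <= 1))
  expect_lte(sum(m$r2x), 1 + 1e-10)
  o <- fit_opls_da(X, y, n_orth = 2)
  # predictive scores uncorrelated with each orthogonal score
  for (k in 1:2)
    expect_lt(abs(cor(m0 <- o$scores[, 1], o$scores_orth[, k])), 1e-8)
  expect_lte(o$r2x + sum(o$r2x_orth), 1 + 1e-10)
})

test_that("OPLS-DA reduces to one-component PLS without orthogonal parts", {
  set.seed(40)
  X <- matrix(rnorm(18 * 6), 18, 6)
  y <- rep(0:1, each = 9)
  o <- fit_opls_da(X, y, n_orth = 0)
  p <- fit_pls_da(X, y, n_components = 1)
  expect_equal(drop(predict(o, X)), drop(predict(p, X)), tolerance = 1e-8)
  expect_identical(o$structure, "1+0+0")
})

test_that("orthogonal filtering strips a planted confounder", {
  set.seed(41)
  n <- 30
  y <- rep(0:1, each = n / 2)
  confounder <- rnorm(n, sd = 4)              # strong, class-unrelated
  d_class <- c(1, 1, 1, 0, 0, 0)              # class direction
  d_conf <- c(0, 0, 0, 1, 1, 1)               # orthogonal direction
  X <- outer(y - mean(y), d_class) + outer(confounder, d_conf) +
    matrix(rnorm(n * 6, sd = 0.1), n, 6)
  o0 <- fit_opls_da(X, y, n_orth = 0)
  o1 <- fit_opls_da(X, y, n_orth = 1)
  expect_gt(abs(cor(o1$scores[, 1], y)), abs(cor(o0$scores[, 1], y)))
  expect_lt(abs(cor(o1$scores_orth[, 1], y)), 1e-8)
  expect_error(fit_opls_da(X, y, n_orth = 10), "rank")
})

test_that("cross-validation approaches 1 for perfectly predictable y", {
  set.seed(42)
  y <- rep(0:1, each = 10)
  X <- cbind(y, y, matrix(rnorm(20 * 3, sd = 1e-3), 20))
  rownames(X) <- sprintf("s%02d", 1:20)
  cv <- cross_validate(X, matrix(y), method = "plsda", n_components = 1)
  expect_gt(cv$q2, 0.99)
})

test_that("Q2 never exceeds R2Y on the same model and data", {
  set.seed(43)
  for (rep in 1:5) {
    X <- matrix(rnorm(24 * 10), 24, 10)
    rownames(X) <- sprintf("s%02d", 1:24)
    y <- rep(0:1, each = 12)
    X[, 1] <- X[, 1] + y * rnorm(1)
    m <- fit_pls_da(X, y, n_components = 2)
    cv <- cross_validate(X, matrix(y), method = "plsda", n_components = 2)
    expect_lte(cv$q2, sum(m$r2y))
  }
})

test_that("label-permuted refits give nonpositive median Q2 on null data", {
  set.seed(44)
  X <- matrix(rnorm(30 * 15), 30, 15)
  rownames(X) <- sprintf("s%02d", 1:30)
  y <- rep(0:1, each = 15)
  q2 <- replicate(50, {
    yp <- sample(y)
    cross_validate(X, matrix(yp), method = "oplsda", n_orth = 0)$q2
  })
  expect_lte(median(q2), 0)
})

test_that("stratification failures are detected", {
  set.seed(45)
  X <- matrix(rnorm(12 * 4), 12, 4)
  rownames(X) <- sprintf("s%02d", 1:12)
  y <- c(1, rep(0, 11))                      # one positive sample only
  expect_error(cross_validate(X, matrix(y), method = "plsda",
                              n_components = 1, k_folds = 7),
               "stratification")
})

test_that("permutation test separates a planted effect from its nulls", {
  set.seed(46)
  n <- 24
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 1:3] <- X[, 1:3] + 3 * y               # strong class effect
  rownames(X) <- sprintf("s%02d", seq_len(n))
  pr <- permutation_test(X, matrix(y), method = "oplsda", n_orth = 0,
                         n_perm = 99, seed = 5)
  expect_equal(pr$p_value, 1 / 100)
  expect_true(all(pr$permutations$q2 < pr$q2_orig))
  expect_true(all(pr$permutations$cor < 1))
  # single permutation: identity excluded, stats differ from original
  pr1 <- permutation_test(X, matrix(y), method = "oplsda", n_orth = 0,
                          n_perm = 1, seed = 6)
  expect_false(isTRUE(all.equal(pr1$permutations$q2, pr1$q2_orig)))
})

test_that("CV-ANOVA limits behave as designed", {
  fake_cv <- function(press, ss, n, a)
    list(press = press, ss = ss, n = n, n_param = a)
  no_gain <- cv_anova(fake_cv(10, 10, 30, 1))
  expect_equal(no_gain$f, 0)
  expect_equal(no_gain$p_value, 1)
  perfect <- cv_anova(fake_cv(1e-9, 10, 30, 1))
  expect_lt(perfect$p_value, 1e-12)
  expect_equal(perfect$df1, 3)               # 2A + 1
  expect_equal(perfect$df2, 29 - 3)
  expect_error(cv_anova(fake_cv(1, 10, 5, 2)), "too few")
})

test_that("VIP normalization identities hold", {
  set.seed(47)
  # single-variable model: VIP is exactly 1
  X1 <- matrix(rnorm(16), 16, 1)
  y <- rep(0:1, each = 8)
  m1 <- fit_pls_da(X1, y, n_components = 1)
  expect_equal(unname(compute_vip(m1)), 1, tolerance = 1e-10)
  # mean squared VIP = 1 for any model
  X <- matrix(rnorm(16 * 7), 16, 7)
  m <- fit_pls_da(X, y, n_components = 2)
  expect_equal(mean(compute_vip(m)^2), 1, tolerance = 1e-8)
  o <- fit_opls_da(X, y, n_orth = 1)
  expect_equal(mean(compute_vip(o)^2), 1, tolerance = 1e-8)
  expect_error(compute_vip(fit_pca(X, 2)), "supervised")
})

test_that("VIP singles out the only informative variable", {
  set.seed(48)
  y <- rep(0:1, each = 12)
  X <- matrix(rnorm(24 * 6, sd = 1), 24, 6)
  X[, 1] <- X[, 1] + 4 * y
  m <- fit_pls_da(X, y, n_components = 1)
  vip <- compute_vip(m)
  expect_equal(unname(which.max(vip)), 1)
  expect_gt(vip[1], 1)
})

test_that("back-scaled loadings undo Pareto scaling linearly", {
  tb <- toy_bucket_table(n = 14, p = 5, shift = 3)
  tn <- normalize_total(tb)
  ps <- pareto_scale(tn)
  y <- tb$meta$group
  m <- fit_opls_da(ps, y, n_orth = 0)
  bs <- backscale_loadings(m, ps)
  expect_equal(nrow(bs), 5)
  expect_true(all(diff(bs$bucket) < 0))      # descending shift order
  expect_equal(bs$backscaled,
               bs$loading * ps$col_sd[match(sprintf("%.4f", bs$bucket),
                                            names(ps$col_sd))],
               ignore_attr = TRUE)
  # sd = 1 identity
  ps1 <- ps; ps1$col_sd[] <- 1
  bs1 <- backscale_loadings(m, ps1)
  expect_equal(bs1$backscaled, bs1$loading)
  # doubling one bucket's sd doubles its back-scaled loading
  ps2 <- ps; ps2$col_sd[2] <- 2 * ps$col_sd[2]
  bs2 <- backscale_loadings(m, ps2)
  b2 <- sprintf("%.4f", ps$centers[2])
  expect_equal(bs2$backscaled[sprintf("%.4f", bs2$bucket) == b2],
               2 * bs$backscaled[sprintf("%.4f", bs$bucket) == b2])
  expect_error(backscale_loadings(m, tn), "Pareto")
})

test_that("the scaled pipeline is invariant to sample order", {
  tb <- toy_bucket_table(n = 16, p = 6, shift = 2)
  tn <- normalize_total(tb)
  perm <- sample(16)
  tp <- tn; tp$X <- tn$X[perm, ]; tp$meta <- tn$meta[perm, ]
  m1 <- fit_opls_da(pareto_scale(tn), tn$meta$group, n_orth = 1)
  m2 <- fit_opls_da(pareto_scale(tp), tp$meta$group, n_orth = 1)
  expect_equal(m1$r2y, m2$r2y, tolerance = 1e-10)
  expect_equal(m1$r2x, m2$r2x, tolerance = 1e-10)
  expect_equal(abs(compute_vip(m1)), abs(compute_vip(m2)), tolerance = 1e-8)
})
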