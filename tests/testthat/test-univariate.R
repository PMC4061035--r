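test_that("candidate selection deduplicates and labels unknowns", {
  map <- data.frame(bucket = c(1.105, 1.115, 3.565),
                    metabolite = c("lactate", "lactate", "glycine"))
  vip <- c("1.1050" = 0.5, "1.1150" = 2.0, "3.5650" = 1.44, "7.2050" = 1.2)
  cand <- select_candidates(vip, map)
  expect_equal(nrow(cand), 3)
  expect_equal(cand$vip[cand$metabolite == "lactate"], 2.0,
               ignore_attr = TRUE)           # max-VIP bucket wins
  expect_true("U1" %in% cand$metabolite)     # unmapped bucket kept as unknown
  # all VIP <= 1: empty list
  expect_equal(nrow(select_candidates(c("1.1050" = 0.9), map)), 0)
  # published VIP pattern: two glucose buckets, one lysine bucket
  map2 <- data.frame(bucket = c(5.225, 3.475, 1.725),
                     metabolite = c("glucose", "glucose", "lysine"))
  vip2 <- c("5.2250" = 4.13, "3.4750" = 3.0, "1.7250" = 1.44)
  cand2 <- select_candidates(vip2, map2)
  expect_equal(cand2$metabolite, c("glucose", "lysine"))
  expect_equal(cand2$vip, c(4.13, 1.44), ignore_attr = TRUE)
})

test_that("the normality gate picks the documented branches", {
  # identical groups: t branch, P = 1
  r <- decision_tree_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$test, "t")
  expect_equal(r$p_value, 1)
  # heavily log-skewed data routes to Mann-Whitney almost always
  set.seed(51)
  picks <- replicate(500, {
    g1 <- exp(rnorm(30, 0, 2)); g2 <- rnorm(30, 5)
    decision_tree_test(g1, g2)$test
  })
  expect_gte(mean(picks == "MannWhitneyU"), 0.95)
  # all-tied data warns and returns P = 1
  expect_warning(tied <- decision_tree_test(rep(2, 5), rep(2, 4)), "tied")
  expect_equal(tied$p_value, 1)
})

test_that("the exact Mann-Whitney case matches rank enumeration", {
  # U = 0 for {1,2,3} vs {4,5,6}: 1 of choose(6,3) = 20 assignments per
  # tail, two-sided P = 2/20 = 0.1
  r <- decision_tree_test(c(1, 2, 3), c(4, 5, 6), branch = "MannWhitneyU")
  expect_equal(r$test, "MannWhitneyU")
  expect_equal(r$p_value, 0.1)
})

test_that("the t branch reproduces the closed form from summary statistics", {
  set.seed(52)
  g1 <- rnorm(21, 10, 2); g2 <- rnorm(16, 11, 2)
  r <- decision_tree_test(g1, g2, branch = "t")
  sp2 <- ((21 - 1) * var(g1) + (16 - 1) * var(g2)) / (21 + 16 - 2)
  tt <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 21 + 1 / 16))
  p <- 2 * pt(-abs(tt), 21 + 16 - 2)
  expect_equal(r$p_value, p, tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(53)
  p <- runif(25)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone in raw order
  expect_true(all(adj <= 1))
})

test_that("fold changes reproduce published arithmetic", {
  expect_equal(fold_change(0.734, 0.672)$printed, 0.92)
  expect_equal(fold_change(0.361, 0.400)$printed, 1.11)
  expect_equal(fold_change(2, 2)$printed, 1.00)
  expect_equal(fold_change(0.70, 0.53)$raw, 0.53 / 0.70)
  expect_error(fold_change(0, 1), "nonpositive")
  # rounding is half-up, not half-even
  expect_equal(round_half_up(1.005, 2), 1.01)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("type-I error of the decision tree is nominal on null data", {
  set.seed(54)
  rej <- replicate(400, {
    g1 <- rnorm(21); g2 <- rnorm(16)
    decision_tree_test(g1, g2)$p_value < 0.05
  })
  ci <- qbinom(c(0.025, 0.975), 400, 0.05)
  expect_gte(sum(rej), ci[1])
  expect_lte(sum(rej), ci[2])
})

test_that("planted genotype effects are recovered at concentration level", {
  # draws at the published group means/SDs and study n; the decision tree
  # should flag most planted metabolites per cohort
  ref <- genotype_reference()
  set.seed(55)
  sens <- replicate(20, {
    hits <- vapply(seq_len(nrow(ref)), function(i) {
      g1 <- rnorm(21, ref$mean_nn[i], ref$sd_nn[i])
      g2 <- rnorm(16, ref$mean_nc[i], ref$sd_nc[i])
      decision_tree_test(abs(g1) + 1e-9, abs(g2) + 1e-9)$p_value < 0.05
    }, TRUE)
    mean(hits)
  })
  expect_gte(mean(sens), 0.6)
})

test_that("run_univariate assembles a coherent metabolite table", {
  tb <- toy_bucket_table(n = 20, p = 6, shift = 4)
  tn <- normalize_total(tb)
  ps <- pareto_scale(tn)
  y <- tb$meta$group
  m <- fit_opls_da(ps, y, n_orth = 0)
  vip <- compute_vip(m)
  map <- data.frame(bucket = tn$centers[1], metabolite = "marker")
  res <- run_univariate(tn, y, vip, map)
  expect_s3_class(res, "metabolite_result")
  expect_true("marker" %in% res$metabolite)
  mk <- res[res$metabolite == "marker", ]
  expect_true(mk$significant)
  expect_equal(mk$fold_change, mk$mean_group2 / mk$mean_group1)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_true(all(res$fold_change > 0))
  expect_equal(res$significant, res$vip > 1 & res$p_value < 0.05)
  # refuses scaled input (tests must run on normalized intensities)
  expect_error(run_univariate(ps, y, vip, map))
  # TSV export mirrors the published layout
  path <- tempfile(fileext = ".tsv")
  write_metabolite_tsv(res, path)
  tsv <- read.delim(path)
  expect_true(all(c("metabolite", "VIP", "fold_change", "bh_p_adj") %in%
                  names(tsv)))
})
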