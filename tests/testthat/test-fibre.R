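test_that("prevalence-weighted overall CSA reconstructs the published value", {
  ref <- fibre_reference()
  sm <- ref[ref$muscle == "semimembranosus", ]
  pct <- sm$normal[sm$variable == "percent"]
  csa <- sm$normal[sm$variable == "csa"]
  overall <- weighted_overall_csa(pct, csa)
  expect_equal(overall, 1635.53, tolerance = 1e-6)
  expect_equal(round_half_up(overall, 0), 1636)
  # degenerate cases
  expect_equal(weighted_overall_csa(c(50, 50, 0, 0, 0), rep(7, 5)), 7)
  expect_equal(weighted_overall_csa(c(100, 0, 0, 0, 0),
                                    c(1512, 1, 1, 1, 1)), 1512)
  # bounded by the per-type extremes
  expect_true(overall >= min(csa) && overall <= max(csa))
  expect_error(weighted_overall_csa(c(50, 50), c(1, 2, 3)), "aligned")
})

test_that("two-group ANOVA matches the hand case and the aov oracle", {
  g1 <- c(10, 12, 14); g2 <- c(20, 22, 24)
  a <- two_group_anova(g1, g2)
  expect_equal(a$mse, 4)
  expect_equal(a$sed, sqrt(4 * (2 / 3)), tolerance = 1e-12)
  expect_equal(a$f, 37.5, tolerance = 1e-12)
  expect_equal(a$p_value, pf(37.5, 1, 4, lower.tail = FALSE))
  # aov oracle
  fit <- summary(aov(v ~ g, data.frame(v = c(g1, g2),
                                       g = rep(c("a", "b"), each = 3))))[[1]]
  expect_equal(a$f, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(a$p_value, fit$`Pr(>F)`[1], tolerance = 1e-10)
  # F = t^2 identity
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(a$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs are handled", {
  same <- two_group_anova(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$f, 0)
  expect_equal(same$p_value, 1)
  ident <- two_group_anova(c(3, 4, 5), c(3, 4, 5))
  expect_equal(ident$f, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1)
  expect_error(two_group_anova(1, c(2, 3)), "at least 2")
})

test_that("s.e.d. halves when both groups quadruple at fixed variance", {
  set.seed(61)
  g1 <- rnorm(200, 10); g2 <- rnorm(200, 12)
  h1 <- rnorm(800, 10); h2 <- rnorm(800, 12)
  a1 <- two_group_anova(g1, g2)
  a4 <- two_group_anova(h1, h2)
  expect_equal(a4$sed / a1$sed, 0.5, tolerance = 0.1)
  # and exactly, from the pooled-error formula at identical MSE
  expect_equal(sqrt(1 * (1 / 24 + 1 / 24)) / sqrt(1 * (1 / 6 + 1 / 6)), 0.5)
})

test_that("genotype ratios reproduce the published arithmetic", {
  expect_equal(genotype_ratio(3227, 1636)$printed, 1.97)
  expect_equal(genotype_ratio(86.4, 65.2)$printed, 1.33)
  expect_equal(genotype_ratio(5, 5)$printed, 1.00)
  expect_error(genotype_ratio(-1, 2), "nonpositive")
})

test_that("simulated fibre tables converge to their targets", {
  # zero-variance reference: every animal equals the group mean
  ref0 <- fibre_reference()
  ref0 <- ref0[ref0$muscle == "semimembranosus", ]
  ref0$sed <- 0
  ft0 <- simulate_fibre_tables("semimembranosus", reference = ref0, seed = 2)
  csa_nn <- ft0[ft0$genotype == "NN", paste0("csa_", c("1", "2C", "2A", "2AX", "2X"))]
  expect_equal(unname(unlist(csa_nn[1, ])),
               ref0$normal[ref0$variable == "csa"])
  expect_true(all(apply(csa_nn, 2, sd) == 0))
  # percentages renormalize to 100
  ft <- simulate_fibre_tables("semimembranosus", seed = 3)
  pct_cols <- paste0("pct_", c("1", "2C", "2A", "2AX", "2X"))
  expect_equal(unname(rowSums(ft[, pct_cols])), rep(100, nrow(ft)),
               tolerance = 1e-9)
  # recovered s.e.d. approaches the input at Monte-Carlo n
  big <- simulate_fibre_tables("semimembranosus", n_per_group = 5000, seed = 4)
  a <- two_group_anova(big$csa_2X[big$genotype == "NN"],
                       big$csa_2X[big$genotype == "NC"])
  ref <- fibre_reference()
  sed_in <- ref$sed[ref$muscle == "semimembranosus" & ref$variable == "csa" &
                    ref$fibre_type == "2X"]
  sd_animal <- sed_in / sqrt(1 / 3 + 1 / 3)       # reference n = 3
  sed_expected <- sqrt(sd_animal^2 * (2 / 5000))
  expect_equal(a$sed, sed_expected, tolerance = 0.05)
  # determinism
  expect_identical(simulate_fibre_tables("semimembranosus", seed = 5),
                   simulate_fibre_tables("semimembranosus", seed = 5))
})

test_that("analysis of a calibrated cohort mirrors the published contrasts", {
  # at the published effect sizes (overall CSA 1636 vs 3227, s.e.d. 368.4,
  # n = 3 per genotype) the genotype contrast is significant at the study's
  # P < 0.05 threshold in nearly every replicate
  set.seed(62)
  hits <- replicate(20, {
    ft <- simulate_fibre_tables("semimembranosus",
                                seed = sample.int(1e6, 1))
    st <- analyze_fibre_table(ft)
    st$p_value[st$variable == "csa_overall"] < 0.05
  })
  expect_gte(mean(hits), 0.75)
  # both overall-CSA variants are reported and close to each other
  ft <- simulate_fibre_tables("semimembranosus", seed = 7)
  st <- analyze_fibre_table(ft)
  alt <- attr(st, "overall_from_group_means")
  ov <- st[st$variable == "csa_overall", ]
  expect_equal(unname(alt["NN"]), ov$normal, tolerance = 0.05)
  expect_equal(unname(alt["NC"]), ov$callipyge, tolerance = 0.05)
  expect_gt(ov$ratio, 1.5)
})
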