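# Metabolite-level univariate statistics: VIP-based candidate selection,
# the normality-gated test choice, BH correction and fold changes.

#' Round half away from zero
#'
#' Plain decimal rounding as printed in summary tables (0.005 -> 0.01),
#' as opposed to R's round-half-even.
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # the epsilon guards against binary representation (1.005 stores below
  # 1.005) pushing a printed half down instead of up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Select candidate metabolites from per-bucket VIPs
#'
#' Keeps buckets with VIP > 1; where several qualifying buckets map to the
#' same metabolite, only the bucket with maximal VIP is retained so each
#' metabolite is represented once. Qualifying buckets without a map entry
#' are retained as distinct unknowns (U1, U2, ... continuing after any
#' unknown names already present in the map).
#'
#' @param vip named numeric vector of per-bucket VIPs (names = bucket
#'   center shifts, as produced by [compute_vip()] on a bucketed model).
#' @param map data frame `bucket`, `metabolite` (see
#'   [bucket_metabolite_map()]).
#' @param threshold VIP cutoff (default 1).
#' @return data frame `metabolite`, `bucket`, `vip`, sorted by metabolite.
#' @export
select_candidates <- function(vip, map, threshold = 1) {
  keep <- which(vip > threshold)
  if (!length(keep))
    return(data.frame(metabolite = character(0), bucket = numeric(0),
                      vip = numeric(0), stringsAsFactors = FALSE))
  buckets <- as.numeric(names(vip)[keep])
  met <- map$metabolite[match(round(buckets, 6), round(map$bucket, 6))]
  n_known_unknowns <- length(grep("^U[0-9]+$", unique(map$metabolite)))
  n_new <- sum(is.na(met))
  if (n_new)
    met[is.na(met)] <- sprintf("U%d", n_known_unknowns + seq_len(n_new))
  df <- data.frame(metabolite = met, bucket = buckets, vip = vip[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$metabolite, -df$vip), ]
  df <- df[!duplicated(df$metabolite), ]
  rownames(df) <- NULL
  df[order(df$metabolite), ]
}

#' Normality-gated two-group test
#'
#' The decision-tree univariate stage: Shapiro-Wilk normality is assessed
#' in each group; if both groups pass at `alpha_normality` the two-sample
#' pooled-variance Student's t test is used, otherwise the two-sided
#' Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise, as implemented by
#' [stats::wilcox.test()]).
#'
#' @param values_group1,values_group2 numeric vectors (n >= 3 each).
#' @param alpha_normality significance level of the normality gate.
#' @param welch use the Welch t statistic instead of pooled variance.
#' @param branch `"auto"` (the normality gate decides, default), or force
#'   `"t"` / `"MannWhitneyU"`.
#' @return list `test` ("t" or "MannWhitneyU"), `p_value`, `normal_p`
#'   (the two Shapiro-Wilk p-values).
#' @export
decision_tree_test <- function(values_group1, values_group2,
                               alpha_normality = 0.05, welch = FALSE,
                               branch = c("auto", "t", "MannWhitneyU")) {
  branch <- match.arg(branch)
  g1 <- values_group1; g2 <- values_group2
  if (length(g1) < 3 || length(g2) < 3)
    stop("each group needs at least 3 observations")
  if (stats::sd(c(g1, g2)) == 0) {
    warning("all values tied; P set to 1")
    return(list(test = "t", p_value = 1, normal_p = c(NA, NA)))
  }
  sw <- function(x) if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
  np <- c(sw(g1), sw(g2))
  if (branch == "t" || (branch == "auto" && all(np > alpha_normality))) {
    p <- stats::t.test(g1, g2, var.equal = !welch)$p.value
    list(test = "t", p_value = p, normal_p = np)
  } else {
    p <- suppressWarnings(stats::wilcox.test(g1, g2)$p.value)
    list(test = "MannWhitneyU", p_value = p, normal_p = np)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Fold change between two group means
#'
#' @param mean_group1,mean_group2 positive group means; the ratio reported
#'   is group2 / group1.
#' @return list `raw` (full precision) and `printed` (rounded half-up to 2
#'   decimals).
#' @export
fold_change <- function(mean_group1, mean_group2) {
  if (mean_group1 <= 0 || mean_group2 <= 0)
    stop("fold change undefined for nonpositive means")
  r <- mean_group2 / mean_group1
  list(raw = r, printed = round_half_up(r, 2))
}

#' Univariate metabolite table for one comparison
#'
#' Combines candidate selection, the decision-tree test, fold changes and
#' BH correction into the per-metabolite result table. Values are taken
#' from each candidate's representative bucket in the normalized
#' (unscaled) bucket table. Metabolites are called significant under the
#' joint rule VIP > 1 and raw P < 0.05 (the BH-adjusted variant is
#' reported alongside).
#'
#' @param table normalized `"bucket_table"` (before Pareto scaling).
#' @param group 0/1 vector aligned with the table rows (group2 = 1).
#' @param vip per-bucket VIP vector (names = bucket centers).
#' @param map bucket-to-metabolite map.
#' @param alpha significance level for the joint rule.
#' @return data frame of class `"metabolite_result"`: `metabolite`,
#'   `bucket`, `vip`, group means/SDs/sizes, `fold_change` (group2 vs
#'   group1, raw) and `fold_printed`, `test`, `p_value`, `p_adjusted`,
#'   `significant`, `significant_adj`.
#' @export
run_univariate <- function(table, group, vip, map, alpha = 0.05) {
  stopifnot(inherits(table, "bucket_table"), table$normalized,
            identical(table$scaling, "none"))
  cand <- select_candidates(vip, map)
  if (!nrow(cand)) {
    return(structure(data.frame(), class = c("metabolite_result", "data.frame")))
  }
  g <- as.numeric(group)
  cols <- match(sprintf("%.4f", cand$bucket), colnames(table$X))
  res <- lapply(seq_len(nrow(cand)), function(i) {
    x <- table$X[, cols[i]]
    x1 <- x[g == 0]; x2 <- x[g == 1]
    tst <- decision_tree_test(x1, x2)
    fc <- fold_change(mean(x1), mean(x2))
    data.frame(metabolite = cand$metabolite[i], bucket = cand$bucket[i],
               vip = cand$vip[i],
               mean_group1 = mean(x1), sd_group1 = stats::sd(x1),
               n_group1 = length(x1),
               mean_group2 = mean(x2), sd_group2 = stats::sd(x2),
               n_group2 = length(x2),
               fold_change = fc$raw, fold_printed = fc$printed,
               test = tst$test, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- bh_adjust(res$p_value)
  res$significant <- res$vip > 1 & res$p_value < alpha
  res$significant_adj <- res$vip > 1 & res$p_adjusted < alpha
  rownames(res) <- NULL
  class(res) <- c("metabolite_result", "data.frame")
  res
}

#' Write a metabolite result table as TSV
#'
#' Columns mirror the published table layout: metabolite, VIP, mean +/- SD
#' per group, fold change, raw and BH-adjusted P, and a flag marking
#' Mann-Whitney-derived P-values.
#' @param result a [run_univariate()] table.
#' @param path output file.
#' @export
write_metabolite_tsv <- function(result, path) {
  out <- data.frame(
    metabolite = result$metabolite,
    VIP = round_half_up(result$vip, 2),
    group1 = sprintf("%.3f±%.3f", result$mean_group1, result$sd_group1),
    group2 = sprintf("%.3f±%.3f", result$mean_group2, result$sd_group2),
    fold_change = sprintf("%.2f", result$fold_printed),
    p_value = signif(result$p_value, 3),
    bh_p_adj = signif(result$p_adjusted, 3),
    mann_whitney = ifelse(result$test == "MannWhitneyU", "d", ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
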