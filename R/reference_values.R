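#' Published reference values for the Callipyge plasma and muscle study
#'
#' Three small tables of published summary statistics ship with the package.
#' They serve two purposes: they parameterize the synthetic-cohort generator
#' (group means, standard deviations and fold changes of the plasma
#' metabolites; fibre-type group means and s.e.d. values), and they provide
#' the worked-example arithmetic that the analysis functions are checked
#' against (fold-change reproduction, prevalence-weighted fibre
#' cross-sectional areas).
#'
#' @return
#' `age_reference()` returns a data frame of per-metabolite plasma summary
#' statistics for the 8 vs 12 week comparison (relative-intensity means and
#' SDs per age, printed fold change, VIP, and whether the published P-value
#' came from the Mann-Whitney U branch).
#'
#' `genotype_reference()` returns the analogous data frame for the wild-type
#' (NN) vs Callipyge (NC) comparison at 12 weeks of age.
#'
#' `fibre_reference()` returns per-muscle, per-variable group means, s.e.d.
#' and group sizes for the myofibre morphometry comparison: percent of
#' myofibres and mean cross-sectional area (um^2) per fibre type
#' (1, 2C, 2A, 2AX, 2X), plus fibre density per mm^2.
#' @name reference_values
NULL

#' @rdname reference_values
#' @export
age_reference <- function() {
  df <- data.frame(
    metabolite = c("acetone", "betaine/TMAO", "creatinine", "formate",
                   "glucose", "glycine", "lysine", "methanol",
                   "myo-inositol", "trimethylamine", "U1", "U2"),
    vip     = c(1.28, 3.28, 1.25, 2.20, 4.13, 5.09, 1.44, 6.37, 1.62, 1.70, 1.07, 1.12),
    mean_8  = c(0.081, 0.668, 0.108, 0.070, 0.734, 0.730, 0.135, 0.315, 0.095, 0.110, 0.071, 0.080),
    sd_8    = c(0.020, 0.056, 0.014, 0.016, 0.073, 0.100, 0.013, 0.274, 0.013, 0.015, 0.008, 0.007),
    mean_12 = c(0.071, 0.625, 0.116, 0.053, 0.672, 0.832, 0.145, 0.153, 0.107, 0.097, 0.077, 0.086),
    sd_12   = c(0.016, 0.044, 0.012, 0.015, 0.055, 0.139, 0.012, 0.023, 0.016, 0.019, 0.008, 0.008),
    fold_printed = c(0.88, 0.94, 1.08, 0.77, 0.92, 1.14, 1.07, 0.49, 1.12, 0.88, 1.08, 1.07),
    mwu = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname reference_values
#' @export
genotype_reference <- function() {
  df <- data.frame(
    metabolite = c("3-hydroxybutyrate", "acetate", "acetone", "alanine",
                   "creatine", "creatinine", "glutamate", "glycine",
                   "lysine", "U3", "U4"),
    vip     = c(2.35, 4.29, 1.36, 1.87, 2.73, 1.08, 2.03, 4.37, 1.52, 4.35, 3.80),
    mean_nn = c(0.361, 0.423, 0.066, 0.243, 0.405, 0.112, 0.224, 0.885, 0.194, 1.074, 1.336),
    sd_nn   = c(0.035, 0.131, 0.007, 0.029, 0.037, 0.010, 0.025, 0.134, 0.017, 0.134, 0.157),
    mean_nc = c(0.400, 0.311, 0.079, 0.218, 0.358, 0.121, 0.198, 0.763, 0.179, 0.955, 1.226),
    sd_nc   = c(0.057, 0.069, 0.021, 0.029, 0.057, 0.012, 0.027, 0.116, 0.017, 0.095, 0.107),
    fold_printed = c(1.11, 0.73, 1.19, 0.90, 0.88, 1.08, 0.88, 0.86, 0.92, 0.89, 0.92),
    mwu = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname reference_values
#' @export
fibre_reference <- function() {
  row <- function(muscle, variable, type, normal, callipyge, sed, n) {
    data.frame(muscle = muscle, variable = variable, fibre_type = type,
               normal = normal, callipyge = callipyge, sed = sed,
               n_per_group = n, stringsAsFactors = FALSE)
  }
  types <- c("1", "2C", "2A", "2AX", "2X")
  sm <- rbind(
    row("semimembranosus", "fibres_per_mm2", NA, 499, 263, 85.3, 3),
    row("semimembranosus", "percent", types,
        c(9.7, 1.9, 18.2, 4.9, 65.2), c(8.5, 0.8, 3.6, 0.7, 86.4),
        c(1.68, 0.51, 2.09, 1.46, 2.67), 3),
    row("semimembranosus", "csa", types,
        c(1512, 1041, 1111, 1305, 1845), c(1468, 1070, 1696, 1757, 3514),
        c(135.1, 342.2, 147.6, 683.6, 483.6), 3),
    row("semimembranosus", "csa_overall", NA, 1636, 3227, 368.4, 3)
  )
  st <- rbind(
    row("semitendinosus", "fibres_per_mm2", NA, 405, 300, 70.3, 4),
    row("semitendinosus", "percent", types,
        c(11.5, 1.2, 19.3, 3.3, 64.8), c(5.4, 0.3, 6.1, 1.7, 86.6),
        c(2.57, 0.28, 2.11, 0.78, 4.54), 4),
    row("semitendinosus", "csa", types,
        c(1811, 1530, 1562, 1789, 2664), c(1282, 2038, 2001, 1791, 2990),
        c(220.2, 1006, 545.1, 326.8, 487.5), 4),
    row("semitendinosus", "csa_overall", NA, 2314, 2808, 457.7, 4)
  )
  ss <- rbind(
    row("supraspinatus", "fibres_per_mm2", NA, 383, 389, 129.1, 4),
    row("supraspinatus", "percent", types,
        c(33.4, 5.4, 10.1, 5.2, 45.9), c(36.6, 4.0, 9.0, 4.0, 46.4),
        c(8.22, 2.65, 0.90, 1.13, 9.43), 4),
    row("supraspinatus", "csa", types,
        c(1931, 1333, 1556, 1728, 2160), c(2014, 1178, 1640, 2001, 2602),
        c(490.9, 380.7, 404.9, 504.8, 568.9), 4),
    row("supraspinatus", "csa_overall", NA, 2018, 2212, 445.4, 4)
  )
  rbind(sm, st, ss)
}

#' Default planted-effect table for the synthetic cohort
#'
#' Builds the per-metabolite effect table that drives
#' [sample_concentrations()]. Baseline means and SDs come from the published
#' group summaries: for metabolites with an age effect the baseline is the
#' 8-week mean, for metabolites only reported in the genotype comparison the
#' baseline is the wild-type 12-week mean (their age fold change is 1), and
#' a few panel metabolites without any reported change (lactate, valine,
#' N-acetyl glycoprotein, glucose's genotype response, ...) carry fold
#' change 1 in every factor. Fold changes are the exact ratios of the
#' reference group means, not the rounded printed values, so that planted
#' truth and group means stay mutually consistent. The genotype effect is
#' planted at 12 weeks only; the 8-week genotype and the gender fold changes
#' default to 1 (the study detected neither).
#'
#' @param null_effects if `TRUE`, all fold changes are set to 1 (a global
#'   null cohort used for type-I-error checks).
#' @return data frame with class `"effect_table"`: `metabolite`,
#'   `baseline_mean`, `baseline_sd`, `age_fc`, `geno12_fc`, `geno8_fc`,
#'   `gender_fc`.
#' @export
default_effects <- function(null_effects = FALSE) {
  t2 <- age_reference()
  t3 <- genotype_reference()

  eff <- data.frame(
    metabolite    = t2$metabolite,
    baseline_mean = t2$mean_8,
    baseline_sd   = t2$sd_8,
    age_fc        = t2$mean_12 / t2$mean_8,
    geno12_fc     = 1,
    stringsAsFactors = FALSE
  )
  # genotype effects at 12 wk; metabolites absent from the age table get the
  # wild-type 12-wk mean as baseline with no age effect
  for (i in seq_len(nrow(t3))) {
    m <- t3$metabolite[i]
    fc <- t3$mean_nc[i] / t3$mean_nn[i]
    j <- match(m, eff$metabolite)
    if (is.na(j)) {
      eff <- rbind(eff, data.frame(
        metabolite = m, baseline_mean = t3$mean_nn[i], baseline_sd = t3$sd_nn[i],
        age_fc = 1, geno12_fc = fc, stringsAsFactors = FALSE))
    } else {
      eff$geno12_fc[j] <- fc
    }
  }
  # panel metabolites with no planted change
  eff <- rbind(eff, data.frame(
    metabolite    = c("lactate", "valine", "N-acetyl glycoprotein"),
    baseline_mean = c(0.90, 0.25, 0.45),
    baseline_sd   = c(0.12, 0.030, 0.050),
    age_fc = 1, geno12_fc = 1, stringsAsFactors = FALSE))

  eff$geno8_fc  <- 1
  eff$gender_fc <- 1
  if (null_effects) {
    eff$age_fc <- 1
    eff$geno12_fc <- 1
  }
  rownames(eff) <- NULL
  validate_effect_table(eff)
  class(eff) <- c("effect_table", "data.frame")
  eff
}

validate_effect_table <- function(eff) {
  stopifnot(is.data.frame(eff),
            all(c("metabolite", "baseline_mean", "baseline_sd",
                  "age_fc", "geno12_fc", "geno8_fc", "gender_fc") %in% names(eff)))
  if (any(eff$baseline_mean <= 0)) stop("effect table: baseline means must be > 0")
  if (any(eff$baseline_sd < 0)) stop("effect table: baseline SDs must be >= 0")
  fc <- as.matrix(eff[, c("age_fc", "geno12_fc", "geno8_fc", "gender_fc")])
  if (any(fc <= 0)) stop("effect table: fold changes must be > 0")
  invisible(eff)
}
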