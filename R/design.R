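#' Build a cohort design
#'
#' Constructs the animal roster and sampling occasions of a two-age plasma
#' cohort. The default mirrors the study design: 17 Callipyge (NC; 8 male,
#' 9 female) and 22 wild-type (NN; 12 male, 10 female) lambs, each sampled
#' at 8 and 12 weeks of age, with two NC samples at 8 weeks unavailable and
#' three samples flagged as outliers (both samples of one diseased NC
#' animal, plus one NN 12-week sample carrying a high level of an unknown
#' metabolite).
#'
#' @param n_nc,n_nn numbers of NC and NN animals.
#' @param missing list of sample specs `list(animal =, age =)` marking
#'   unavailable samples; `NULL` for the default (two NC animals at 8 wk)
#'   when the roster is the default one, otherwise none.
#' @param outliers list of sample specs `list(animal =, age =, mode =)`
#'   with `mode` one of `"diseased"` or `"unknown_metabolite"`; `NULL` for
#'   the default three flags on the default roster, otherwise none.
#' @param seed recorded in the design for provenance (the roster itself is
#'   deterministic).
#' @return data frame of class `"cohort_design"`, one row per (animal, age)
#'   sample: `sample_id`, `animal_id`, `genotype`, `gender`, `age_wk`,
#'   `present`, `outlier_mode` (NA when not flagged).
#' @export
build_design <- function(n_nc = 17, n_nn = 22, missing = NULL, outliers = NULL,
                         seed = NULL) {
  stopifnot(n_nc >= 0, n_nn >= 0)
  default_roster <- (n_nc == 17 && n_nn == 22)
  gender_nc <- if (default_roster) rep(c("M", "F"), c(8, 9)) else
    rep_len(c("M", "F"), n_nc)
  gender_nn <- if (default_roster) rep(c("M", "F"), c(12, 10)) else
    rep_len(c("M", "F"), n_nn)
  animals <- data.frame(
    animal_id = c(sprintf("NC%02d", seq_len(n_nc)), sprintf("NN%02d", seq_len(n_nn))),
    genotype  = rep(c("NC", "NN"), c(n_nc, n_nn)),
    gender    = c(gender_nc, gender_nn),
    stringsAsFactors = FALSE
  )
  des <- merge(animals, data.frame(age_wk = c(8L, 12L)), by = NULL)
  des <- des[order(des$animal_id, des$age_wk), ]
  des$sample_id <- sprintf("%s_%02d", des$animal_id, des$age_wk)
  des$present <- TRUE
  des$outlier_mode <- NA_character_

  if (is.null(missing)) {
    missing <- if (default_roster)
      list(list(animal = "NC16", age = 8), list(animal = "NC17", age = 8))
    else list()
  }
  if (is.null(outliers)) {
    outliers <- if (default_roster)
      list(list(animal = "NC05", age = 8,  mode = "diseased"),
           list(animal = "NC05", age = 12, mode = "diseased"),
           list(animal = "NN11", age = 12, mode = "unknown_metabolite"))
    else list()
  }

  locate <- function(sp, what) {
    key <- sprintf("%s_%02d", sp$animal, as.integer(sp$age))
    i <- match(key, des$sample_id)
    if (is.na(i))
      stop("invalid design: ", what, " spec ", key, " does not name a sample")
    i
  }
  mi <- vapply(missing, locate, 0L, what = "missing")
  oi <- vapply(outliers, locate, 0L, what = "outlier")
  if (anyDuplicated(mi) || anyDuplicated(oi) || length(intersect(mi, oi)))
    stop("invalid design: duplicate sample specification")
  des$present[mi] <- FALSE
  for (k in seq_along(outliers)) {
    mode <- outliers[[k]]$mode
    if (!mode %in% c("diseased", "unknown_metabolite"))
      stop("invalid design: unknown outlier mode ", mode)
    des$outlier_mode[oi[k]] <- mode
  }
  rownames(des) <- NULL
  des <- des[, c("sample_id", "animal_id", "genotype", "gender", "age_wk",
                 "present", "outlier_mode")]
  attr(des, "seed") <- seed
  class(des) <- c("cohort_design", "data.frame")
  des
}

#' Sample metabolite concentrations for a cohort
#'
#' Draws one relative concentration per (present sample, metabolite). The
#' expected value in cell (genotype g, age a, gender s) is
#' `baseline * age_fc^[a = 12] * geno_fc(a)^[g = NC] * gender_fc^[s = F]`.
#' Noise is multiplicative by default: the SD scales with the planted mean
#' so the coefficient of variation implied by the baseline summary is
#' preserved across cells. Truncated-normal draws are redrawn until
#' positive; the lognormal alternative matches the target mean and CV
#' exactly.
#'
#' @param design a [build_design()] data frame.
#' @param effects an effect table, see [default_effects()].
#' @param noise_model `"truncated-normal"` (default) or `"lognormal"`.
#' @param sd_mode `"proportional"` (SD scales with the planted mean;
#'   default) or `"fixed"` (baseline SD in every cell).
#' @param seed integer seed; draws are reproducible given the seed.
#' @return list with `concentrations` (matrix, present samples x
#'   metabolites) and `manifest` (the planted ground truth: per metabolite,
#'   the fold changes and whether it carries an age or genotype effect).
#' @export
sample_concentrations <- function(design, effects,
                                  noise_model = c("truncated-normal", "lognormal"),
                                  sd_mode = c("proportional", "fixed"),
                                  seed = 1L) {
  noise_model <- match.arg(noise_model)
  sd_mode <- match.arg(sd_mode)
  validate_effect_table(effects)
  des <- design[design$present, ]
  set.seed(seed)

  n <- nrow(des)
  m <- nrow(effects)
  conc <- matrix(NA_real_, n, m,
                 dimnames = list(des$sample_id, effects$metabolite))
  for (j in seq_len(m)) {
    e <- effects[j, ]
    mu <- e$baseline_mean *
      ifelse(des$age_wk == 12, e$age_fc, 1) *
      ifelse(des$genotype == "NC" & des$age_wk == 12, e$geno12_fc, 1) *
      ifelse(des$genotype == "NC" & des$age_wk == 8, e$geno8_fc, 1) *
      ifelse(des$gender == "F", e$gender_fc, 1)
    sdv <- if (sd_mode == "proportional") e$baseline_sd * mu / e$baseline_mean
           else rep(e$baseline_sd, n)
    if (noise_model == "truncated-normal") {
      x <- stats::rnorm(n, mu, sdv)
      bad <- which(x <= 0)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), mu[bad], sdv[bad])
        bad <- bad[x[bad] <= 0]
      }
    } else {
      cv2 <- (sdv / mu)^2
      sdlog <- sqrt(log1p(cv2))
      x <- stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
    }
    conc[, j] <- x
  }
  manifest <- data.frame(
    metabolite = effects$metabolite,
    age_fc = effects$age_fc,
    geno12_fc = effects$geno12_fc,
    geno8_fc = effects$geno8_fc,
    gender_fc = effects$gender_fc,
    age_effect = abs(effects$age_fc - 1) > 1e-12,
    genotype12_effect = abs(effects$geno12_fc - 1) > 1e-12,
    stringsAsFactors = FALSE
  )
  list(concentrations = conc, manifest = manifest, seed = seed)
}
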