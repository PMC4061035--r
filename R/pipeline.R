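# End-to-end orchestration: simulate (or accept) spectra, reference,
# bucket, normalize, PCA outlier pass, Pareto scale, per-comparison
# supervised models with validation, univariate tables, pathway
# enrichment, fibre morphometry, and report output.

#' Pipeline configuration
#'
#' Assembles the settings of a full analysis run. The defaults reproduce
#' the study design: the default synthetic cohort, 0.01 ppm buckets over
#' 9.0-0.5 ppm with the seven exclusion windows, total-intensity
#' normalization to 100, a 5-component PCA outlier pass at the 95%
#' Hotelling bound, and four supervised comparisons — age (all samples,
#' 3 orthogonal components), genotype at 12 and at 8 weeks (1 orthogonal
#' component each), and gender — validated with 7-fold cross-validation,
#' 200 permutations and CV-ANOVA.
#'
#' @param seed master seed, recorded in every output.
#' @param effects planted-effect table ([default_effects()]).
#' @param axis spectral [axis_spec()].
#' @param spec [bucket_spec()].
#' @param comparisons named list: each entry
#'   `list(variable =, age_subset =, n_orth =)`.
#' @param n_perm permutations for model validation (0 disables).
#' @param k_folds cross-validation folds.
#' @param pca_components components of the outlier-screen PCA.
#' @param hotelling_alpha significance of the outlier bound.
#' @param pathway_libraries library names for enrichment.
#' @param fibre_muscles muscles to simulate and analyse (NULL disables).
#' @param alpha univariate significance level.
#' @param out_dir directory for report files (NULL: in-memory only).
#' @param ... overrides passed to [simulate_cohort()] (e.g. `noise_sd`).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            effects = default_effects(),
                            axis = axis_spec(),
                            spec = bucket_spec(),
                            comparisons = list(
                              age        = list(variable = "age",      age_subset = NULL, n_orth = 3),
                              genotype12 = list(variable = "genotype", age_subset = 12,   n_orth = 1),
                              genotype8  = list(variable = "genotype", age_subset = 8,    n_orth = 1),
                              gender     = list(variable = "gender",   age_subset = NULL, n_orth = 1)),
                            n_perm = 200, k_folds = 7,
                            pca_components = 5, hotelling_alpha = 0.05,
                            pathway_libraries = c("toy-hsa", "toy-bta"),
                            fibre_muscles = "semimembranosus",
                            alpha = 0.05, out_dir = NULL, ...) {
  structure(list(seed = seed, effects = effects, axis = axis, spec = spec,
                 comparisons = comparisons, n_perm = n_perm,
                 k_folds = k_folds, pca_components = pca_components,
                 hotelling_alpha = hotelling_alpha,
                 pathway_libraries = pathway_libraries,
                 fibre_muscles = fibre_muscles, alpha = alpha,
                 out_dir = out_dir, simulate_args = list(...)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in study order: simulate (or load) spectra ->
#' chemical-shift referencing -> bucketing -> total-intensity
#' normalization -> PCA + Hotelling outlier exclusion on the Pareto-scaled
#' table (once, on all samples, before any split) -> per-comparison
#' PLS-DA and OPLS-DA with Q2, permutation test and CV-ANOVA -> VIP
#' candidate selection and univariate tables -> pathway enrichment of the
#' significant metabolites -> fibre morphometry. Every exclusion is
#' logged with the rule that caused it; when `out_dir` is set, result
#' tables (TSV), model summaries (JSON) and the stage log are written
#' there.
#'
#' @param config a [pipeline_config()].
#' @param spectra optional named list of `"nmr_spectrum"` objects to
#'   analyse instead of simulating (metadata is taken from each
#'   spectrum's `meta`).
#' @return list of class `"pipeline_result"`: `design`, `n_analysed`,
#'   `excluded_outliers`, `pca`, `tables` (normalized + scaled),
#'   `comparisons` (per comparison: models, validation, univariate
#'   table), `enrichment`, `fibre`, `log`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), spectra = NULL) {
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  library <- load_peak_library()

  # --- simulate / load -------------------------------------------------
  sim <- NULL
  if (is.null(spectra)) {
    sim <- stage("simulate", do.call(simulate_cohort, c(
      list(design = build_design(seed = config$seed),
           effects = config$effects, library = library, axis = config$axis,
           seed = config$seed), config$simulate_args)))
    spectra <- sim$spectra
    meta <- sim$design[sim$design$present,
                       c("sample_id", "animal_id", "genotype", "age_wk", "gender")]
    say("simulate: %d present samples (seed %d)", length(spectra), config$seed)
  } else {
    meta <- do.call(rbind, lapply(spectra, function(s)
      data.frame(sample_id = s$sample_id,
                 animal_id = s$meta$animal_id %||% s$sample_id,
                 genotype = s$meta$genotype, age_wk = s$meta$age_wk,
                 gender = s$meta$gender, stringsAsFactors = FALSE)))
    say("load: %d external spectra", length(spectra))
  }

  # --- reference -------------------------------------------------------
  spectra <- stage("reference", lapply(spectra, function(s) {
    withCallingHandlers(
      reference_spectrum(s),
      warning = function(w) {
        say("reference: %s: %s", s$sample_id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }))

  # --- bucket + normalize ----------------------------------------------
  table_raw <- stage("bucket", build_bucket_table(spectra, config$spec, meta))
  say("bucket: %d buckets retained (%d excluded by windows)",
      ncol(table_raw$X), sum(bucket_spans(config$spec)$excluded))
  table_norm <- stage("normalize", normalize_total(table_raw))

  # --- PCA outlier pass (all samples, before any split) ----------------
  scaled_all <- stage("pareto", pareto_scale(table_norm))
  pca <- stage("pca", fit_pca(scaled_all, config$pca_components))
  hot <- stage("hotelling", hotelling_outliers(pca, config$hotelling_alpha))
  for (id in hot$flagged)
    say("outlier: %s excluded (Hotelling T2 %.1f > %.1f at alpha %.2f)",
        id, hot$t2[id], hot$threshold, config$hotelling_alpha)
  keep <- !rownames(table_norm$X) %in% hot$flagged
  table_norm <- subset_bucket_table(table_norm, keep)
  say("cohort: %d samples analysed after exclusions", nrow(table_norm$X))

  map <- bucket_metabolite_map(library, config$spec)

  # --- supervised comparisons ------------------------------------------
  comparisons <- list()
  for (nm in names(config$comparisons)) {
    cc <- config$comparisons[[nm]]
    rows <- if (is.null(cc$age_subset)) rep(TRUE, nrow(table_norm$X))
            else table_norm$meta$age_wk == cc$age_subset
    sub_norm <- subset_bucket_table(table_norm, rows)
    sub_scaled <- pareto_scale(sub_norm)
    y <- class_table(sub_norm$meta, cc$variable)
    res <- stage(paste0("model:", nm), {
      plsda <- fit_pls_da(sub_scaled, y)
      oplsda <- fit_opls_da(sub_scaled, y[, 1], n_orth = cc$n_orth)
      cv <- cross_validate(sub_scaled, y[, 1, drop = FALSE],
                           method = "oplsda", n_orth = cc$n_orth,
                           k_folds = config$k_folds)
      anova <- cv_anova(cv)
      perm <- if (config$n_perm > 0)
        permutation_test(sub_scaled, y[, 1, drop = FALSE],
                         method = "oplsda", n_orth = cc$n_orth,
                         k_folds = config$k_folds, n_perm = config$n_perm,
                         seed = config$seed + 17L)
      else NULL
      vip <- compute_vip(oplsda)
      uni <- run_univariate(sub_norm, y[, 1], vip, map, alpha = config$alpha)
      list(name = nm, n = nrow(sub_norm$X), y = y, plsda = plsda,
           oplsda = oplsda, q2 = cv$q2, cv = cv, cv_anova = anova,
           permutation = perm, vip = vip, univariate = uni,
           scaled_table = sub_scaled)
    })
    say("model %s: n = %d, A = %s, R2X(pred) = %.3f, R2Y = %.3f, Q2 = %.3f, P(CV-ANOVA) = %.3g%s",
        nm, res$n, res$oplsda$structure, res$oplsda$r2x, res$oplsda$r2y,
        res$q2, res$cv_anova$p_value,
        if (!is.null(res$permutation))
          sprintf(", perm p = %.4g", res$permutation$p_value) else "")
    comparisons[[nm]] <- res
  }

  # --- pathway enrichment ----------------------------------------------
  enrichment <- list()
  for (nm in names(comparisons)) {
    uni <- comparisons[[nm]]$univariate
    if (!nrow(uni)) next
    sig <- uni$metabolite[uni$significant]
    if (!length(sig)) next
    for (lib in config$pathway_libraries) {
      enr <- stage(paste0("enrichment:", nm, ":", lib),
                   suppressWarnings(run_enrichment(sig, lib)))
      enrichment[[paste(nm, lib, sep = ":")]] <- enr
      say("enrichment %s/%s: %d significant pathways",
          nm, lib, sum(enr$significant))
    }
  }

  # --- fibre morphometry -----------------------------------------------
  fibre <- NULL
  if (!is.null(config$fibre_muscles)) {
    fibre <- lapply(config$fibre_muscles, function(m) {
      ft <- simulate_fibre_tables(m, seed = config$seed + 29L)
      list(muscle = m, table = ft, stats = analyze_fibre_table(ft))
    })
    names(fibre) <- config$fibre_muscles
  }

  result <- structure(
    list(design = if (is.null(sim)) NULL else sim$design,
         manifest = if (is.null(sim)) NULL else sim$manifest,
         n_analysed = nrow(table_norm$X),
         excluded_outliers = hot$flagged, hotelling = hot, pca = pca,
         table_normalized = table_norm,
         comparisons = comparisons, enrichment = enrichment,
         fibre = fibre, log = log, seed = config$seed, config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_report(result, config$out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a pipeline configuration from a YAML scenario file
#'
#' Reads a flat YAML scenario — any of the scalar settings of
#' [pipeline_config()] (`seed`, `n_perm`, `k_folds`, `pca_components`,
#' `hotelling_alpha`, `alpha`, `out_dir`, `fibre_muscles`,
#' `pathway_libraries`, `null_effects`, and the simulate overrides
#' `noise_sd`, `baseline_amplitude`, `macromolecules`, `ppm_jitter_sd`) —
#' and returns the corresponding configuration.
#'
#' @param path YAML file.
#' @return a `"pipeline_config"`.
#' @export
pipeline_config_from_yaml <- function(path) {
  sc <- yaml::read_yaml(path)
  if (isTRUE(sc$null_effects)) {
    sc$effects <- default_effects(null_effects = TRUE)
    sc$null_effects <- NULL
  }
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(sc), c(known, "noise_sd", "baseline_amplitude",
                                "macromolecules", "ppm_jitter_sd",
                                "edta_amplitude", "water_area", "urea_area"))
  if (length(extra)) stop("unknown scenario settings: ",
                          paste(extra, collapse = ", "))
  do.call(pipeline_config, sc)
}

#' Write a pipeline report bundle
#'
#' Emits per-comparison univariate TSVs (published-table layout), JSON
#' model summaries with validation records, enrichment TSVs, fibre
#' statistics and the stage log into a directory.
#'
#' @param result a `"pipeline_result"`.
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$comparisons)) {
    cm <- result$comparisons[[nm]]
    if (nrow(cm$univariate))
      write_metabolite_tsv(cm$univariate,
                           file.path(out_dir, paste0("univariate_", nm, ".tsv")))
    summary <- list(
      comparison = nm, n = cm$n, structure = cm$oplsda$structure,
      r2x_pred = cm$oplsda$r2x, r2x_orth = cm$oplsda$r2x_orth,
      r2y = cm$oplsda$r2y, q2 = cm$q2,
      cv_anova = cm$cv_anova[c("f", "df1", "df2", "p_value")],
      permutation_p = if (!is.null(cm$permutation)) cm$permutation$p_value,
      seed = result$seed)
    jsonlite::write_json(summary, file.path(out_dir, paste0("model_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  for (nm in names(result$enrichment)) {
    utils::write.table(result$enrichment[[nm]],
                       file.path(out_dir, paste0("enrichment_",
                                                 gsub(":", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$fibre)) {
    for (m in names(result$fibre))
      utils::write.table(result$fibre[[m]]$stats,
                         file.path(out_dir, paste0("fibre_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(result$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$n_analysed, "samples analysed;",
      length(x$excluded_outliers), "outliers excluded\n")
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    cat(sprintf("  %-10s n=%2d A=%s Q2=%6.3f  perm p=%s  significant metabolites: %d\n",
                nm, cm$n, cm$oplsda$structure, cm$q2,
                if (is.null(cm$permutation)) "NA"
                else format(cm$permutation$p_value, digits = 3),
                sum(cm$univariate$significant %||% 0)))
  }
  invisible(x)
}
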