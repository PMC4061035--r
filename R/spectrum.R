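#' Spectral axis specification
#'
#' @param min_ppm,max_ppm axis limits in ppm.
#' @param points number of data points. The default (32768 points over
#'   9.5-0.0 ppm, stored descending as spectrometers deliver them) gives a
#'   step of ~0.00029 ppm, comfortably resolving the default 0.003 ppm
#'   linewidth.
#' @param descending store the axis high-to-low (TRUE, default)?
#' @return list of class `"axis_spec"`.
#' @export
axis_spec <- function(min_ppm = 0, max_ppm = 9.5, points = 32768L,
                      descending = TRUE) {
  stopifnot(max_ppm > min_ppm, points >= 2)
  structure(list(min_ppm = min_ppm, max_ppm = max_ppm,
                 points = as.integer(points), descending = descending),
            class = "axis_spec")
}

axis_ppm <- function(axis) {
  x <- seq(axis$min_ppm, axis$max_ppm, length.out = axis$points)
  if (axis$descending) rev(x) else x
}

new_spectrum <- function(sample_id, ppm, intensity, meta = list(),
                         provenance = list()) {
  stopifnot(length(ppm) == length(intensity))
  if (!all(is.finite(intensity))) stop("spectrum intensities must be finite")
  structure(list(sample_id = sample_id, ppm = ppm, intensity = intensity,
                 meta = meta, provenance = provenance),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat("<nmr_spectrum>", x$sample_id, ":", length(x$ppm), "points,",
      sprintf("%.2f-%.2f ppm\n", min(x$ppm), max(x$ppm)))
  invisible(x)
}

# Sum of unit-area Lorentzian lines for one resonance, evaluated on ppm.
# Lines are windowed at +/- window_fwhm linewidths (the truncated tail mass
# is ~0.3% at the default 100 linewidths), which keeps rendering linear in
# the number of points actually covered by signal.
lorentzian_lines <- function(ppm, centers, areas, fwhm, window_fwhm = 100) {
  y <- numeric(length(ppm))
  gam <- fwhm / 2
  halfwin <- window_fwhm * fwhm
  for (k in seq_along(centers)) {
    idx <- which(abs(ppm - centers[k]) <= halfwin)
    if (!length(idx)) next
    d <- ppm[idx] - centers[k]
    y[idx] <- y[idx] + areas[k] * gam / (pi * (d^2 + gam^2))
  }
  y
}

render_metabolite <- function(ppm, metab, conc, window_fwhm = 100) {
  y <- numeric(length(ppm))
  for (r in metab$resonances) {
    y <- y + lorentzian_lines(ppm, r$center + r$offsets,
                              conc * r$protons * r$heights, r$fwhm,
                              window_fwhm)
  }
  y
}

#' Render a synthetic 1D 1H spectrum
#'
#' Sums unit-area Lorentzian multiplets for every metabolite (line area =
#' concentration x proton weight x relative line height), adds a smooth
#' polynomial baseline, optionally broad macromolecule humps (emulating a
#' NOESY-type spectrum; the default off-state emulates the CPMG spin-echo
#' filter that suppresses them), and Gaussian noise.
#'
#' @param concentrations named numeric vector of relative concentrations;
#'   names must exist in the library.
#' @param library a [load_peak_library()] object.
#' @param axis an [axis_spec()]; must cover 0.5-9.0 ppm.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param baseline_amplitude amplitude of the smooth baseline arc.
#' @param macromolecules add broad lipid/protein humps?
#' @param sample_id,meta identifiers carried in the output.
#' @param seed seed for the noise draw.
#' @return an `"nmr_spectrum"` object; the concentrations used are retained
#'   in its provenance so that artifact injection can re-render individual
#'   components exactly.
#' @export
render_spectrum <- function(concentrations, library, axis = axis_spec(),
                            noise_sd = 0.2, baseline_amplitude = 0.3,
                            macromolecules = FALSE,
                            sample_id = "sample", meta = list(), seed = NULL) {
  if (axis$min_ppm > 0.5 || axis$max_ppm < 9.0)
    stop("axis must cover 0.5-9.0 ppm")
  nms <- peak_library_names(library)
  if (!all(names(concentrations) %in% nms))
    stop("unknown metabolites: ",
         paste(setdiff(names(concentrations), nms), collapse = ", "))
  ppm <- axis_ppm(axis)
  step <- (axis$max_ppm - axis$min_ppm) / (axis$points - 1)
  min_fwhm <- min(vapply(library$metabolites,
                         function(m) min(vapply(m$resonances, `[[`, 0, "fwhm")), 0))
  if (min_fwhm / step < 4)
    warning(sprintf(
      "axis step %.2g ppm gives < 4 points per narrowest linewidth (%.2g ppm)",
      step, min_fwhm))

  y <- numeric(length(ppm))
  for (m in library$metabolites) {
    conc <- concentrations[m$name]
    if (is.na(conc) || conc == 0) next
    y <- y + render_metabolite(ppm, m, conc)
  }
  # smooth baseline: a gentle arc over the full width
  if (baseline_amplitude != 0) {
    u <- (ppm - axis$min_ppm) / (axis$max_ppm - axis$min_ppm)
    y <- y + baseline_amplitude * (0.5 + u * (1 - u))
  }
  if (macromolecules) {
    for (hump in list(c(0.9, 0.25), c(1.3, 0.25), c(2.0, 0.2), c(3.2, 0.2))) {
      y <- y + lorentzian_lines(ppm, hump[1], hump[2] * 20, fwhm = 0.3,
                                window_fwhm = 5)
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(ppm), 0, noise_sd)
  }
  new_spectrum(sample_id, ppm, y, meta,
               provenance = list(seed = seed,
                                 concentrations = concentrations,
                                 noise_sd = noise_sd))
}

#' EDTA exclusion windows and artifact positions
#'
#' The five chemical-shift windows containing Ca/Mg-EDTA signals in plasma
#' collected into EDTA tubes, plus the urea and residual-water windows, all
#' of which are excluded from bucketing.
#' @return list with `edta` (5 x 2 matrix), `water`, `urea` (ranges in ppm).
#' @export
artifact_windows <- function() {
  list(
    edta = matrix(c(3.60, 3.63, 3.20, 3.23, 3.07, 3.15, 2.68, 2.70, 2.53, 2.58),
                  ncol = 2, byrow = TRUE),
    water = c(4.68, 5.20),
    urea = c(5.60, 6.00)
  )
}

# Peak evaluated only inside [lo, hi], with a small interior margin so
# that trapezoid integration of adjacent buckets (which interpolates
# linearly across the window boundary) picks up none of the artifact:
# artifacts stay strictly confined to the windows that bucketing excludes.
confined_peak <- function(ppm, center, area, fwhm, lo, hi, margin = 0.002) {
  y <- numeric(length(ppm))
  idx <- which(ppm >= lo + margin & ppm <= hi - margin)
  if (!length(idx)) return(y)
  gam <- fwhm / 2
  d <- ppm[idx] - center
  y[idx] <- area * gam / (pi * (d^2 + gam^2))
  y
}

#' Inject instrumental and physiological artifacts into a spectrum
#'
#' Adds, in this order: EDTA peaks confined to the five EDTA exclusion
#' windows; a residual-water hump confined to 4.68-5.20 ppm; a urea signal
#' confined to 5.60-6.00 ppm; an outlier transformation (`"diseased"`:
#' glucose signal removed and lactate scaled tenfold, re-rendered exactly
#' from the concentrations stored in the spectrum's provenance;
#' `"unknown_metabolite"`: a strong alien singlet at 6.15 ppm); and finally
#' a global ppm miscalibration offset applied to the axis.
#'
#' @param spectrum an `"nmr_spectrum"`.
#' @param library peak library (needed for the outlier modes).
#' @param edta_amplitude total EDTA signal area (0 disables).
#' @param water_area,urea_area areas of the water hump and urea signal.
#' @param ppm_offset global calibration offset epsilon added to the axis.
#' @param outlier_mode `NULL`, `"diseased"` or `"unknown_metabolite"`.
#' @param unknown_area area of the alien singlet for the unknown mode.
#' @return the transformed `"nmr_spectrum"` (pure transformation, no RNG).
#' @export
inject_artifacts <- function(spectrum, library = NULL, edta_amplitude = 1,
                             water_area = 10, urea_area = 1, ppm_offset = 0,
                             outlier_mode = NULL, unknown_area = 5) {
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  win <- artifact_windows()
  if (edta_amplitude > 0) {
    centers <- c(3.615, 3.215, 3.11, 2.69, 2.555)
    for (k in 1:5) {
      y <- y + confined_peak(ppm, centers[k], edta_amplitude / 5, 0.004,
                             win$edta[k, 1], win$edta[k, 2])
    }
  }
  if (water_area > 0)
    y <- y + confined_peak(ppm, 4.90, water_area, 0.10,
                           win$water[1], win$water[2])
  if (urea_area > 0)
    y <- y + confined_peak(ppm, 5.78, urea_area, 0.01,
                           win$urea[1], win$urea[2])

  if (!is.null(outlier_mode)) {
    conc <- spectrum$provenance$concentrations
    if (outlier_mode == "diseased") {
      if (is.null(library) || is.null(conc))
        stop("diseased mode needs the library and stored concentrations")
      glc <- library$metabolites[[match("glucose", peak_library_names(library))]]
      lac <- library$metabolites[[match("lactate", peak_library_names(library))]]
      if (!is.na(conc["glucose"]) && conc["glucose"] > 0)
        y <- y - render_metabolite(ppm, glc, conc["glucose"])
      if (!is.na(conc["lactate"]) && conc["lactate"] > 0)
        y <- y + 9 * render_metabolite(ppm, lac, conc["lactate"])
    } else if (outlier_mode == "unknown_metabolite") {
      y <- y + lorentzian_lines(ppm, 6.15, unknown_area, 0.004)
    } else stop("unknown outlier mode: ", outlier_mode)
  }
  if (ppm_offset != 0) ppm <- ppm + ppm_offset
  prov <- spectrum$provenance
  prov$artifacts <- list(edta = edta_amplitude, water = water_area,
                         urea = urea_area, ppm_offset = ppm_offset,
                         outlier_mode = outlier_mode)
  new_spectrum(spectrum$sample_id, ppm, y, spectrum$meta, prov)
}

#' Write / read a spectrum as two-column CSV
#'
#' @param spectrum an `"nmr_spectrum"`.
#' @param path file path.
#' @return `read_spectrum_csv()` returns an `"nmr_spectrum"` (metadata
#'   beyond the trace itself is not round-tripped).
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param sample_id identifier for the read spectrum.
#' @export
read_spectrum_csv <- function(path, sample_id = basename(path)) {
  df <- utils::read.csv(path)
  new_spectrum(sample_id, df$ppm, df$intensity)
}

#' Simulate a full synthetic cohort of plasma spectra
#'
#' Draws concentrations for every present sample of the design, renders one
#' spectrum per sample and injects artifacts (including the design's outlier
#' modes and an optional per-sample random ppm miscalibration).
#'
#' @param design a [build_design()] roster.
#' @param effects an effect table ([default_effects()]).
#' @param library peak library; packaged default when `NULL`.
#' @param axis an [axis_spec()].
#' @param seed master seed; per-sample render seeds are derived from it.
#' @param ppm_jitter_sd SD of the per-sample global ppm offset (set 0 to
#'   disable miscalibration).
#' @param noise_sd,baseline_amplitude,macromolecules passed to
#'   [render_spectrum()].
#' @param edta_amplitude,water_area,urea_area passed to [inject_artifacts()].
#' @return list with `spectra` (named list of `"nmr_spectrum"`), `design`,
#'   `concentrations`, `manifest` (planted ground truth), `seed`.
#' @export
simulate_cohort <- function(design = build_design(), effects = default_effects(),
                            library = NULL, axis = axis_spec(), seed = 1L,
                            ppm_jitter_sd = 0.005, noise_sd = 0.2,
                            baseline_amplitude = 0.3, macromolecules = FALSE,
                            edta_amplitude = 1, water_area = 10, urea_area = 1) {
  if (is.null(library)) library <- load_peak_library()
  cs <- sample_concentrations(design, effects, seed = seed)
  des <- design[design$present, ]
  set.seed(seed + 1L)
  offsets <- stats::rnorm(nrow(des), 0, ppm_jitter_sd)
  spectra <- vector("list", nrow(des))
  names(spectra) <- des$sample_id
  for (i in seq_len(nrow(des))) {
    sp <- render_spectrum(
      cs$concentrations[i, ], library, axis,
      noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
      macromolecules = macromolecules,
      sample_id = des$sample_id[i],
      meta = list(animal_id = des$animal_id[i], genotype = des$genotype[i],
                  age_wk = des$age_wk[i], gender = des$gender[i]),
      seed = seed + 1000L + i)
    mode <- des$outlier_mode[i]
    sp <- inject_artifacts(sp, library,
                           edta_amplitude = edta_amplitude,
                           water_area = water_area, urea_area = urea_area,
                           ppm_offset = offsets[i],
                           outlier_mode = if (is.na(mode)) NULL else mode)
    spectra[[i]] <- sp
  }
  list(spectra = spectra, design = design,
       concentrations = cs$concentrations, manifest = cs$manifest, seed = seed)
}
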