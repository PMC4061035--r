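#' Load a metabolite peak library
#'
#' A peak library describes, per metabolite, the 1H resonances used to render
#' synthetic plasma spectra: multiplet center (ppm), relative line offsets
#' (ppm) with relative line heights summing to 1, Lorentzian full width at
#' half maximum (ppm), and a proton-count weight so that the integrated
#' signal of a metabolite is proportional to concentration x protons. The
#' packaged default covers the plasma panel of the Callipyge study,
#' including the glucose anomeric proton at 5.233 ppm that anchors
#' chemical-shift referencing.
#'
#' @param path path to a library JSON file; the packaged default is used
#'   when omitted.
#' @return object of class `"peak_library"`: a list with `name` and
#'   `metabolites` (each metabolite a list with `name`, `synonyms`,
#'   `resonances`).
#' @export
load_peak_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "peak_library.json", package = "ovimetab",
                        mustWork = TRUE)
  }
  lib <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib$metabolites <- lapply(lib$metabolites, function(m) {
    m$synonyms <- as.character(unlist(m$synonyms))
    m$resonances <- lapply(m$resonances, function(r) {
      r$offsets <- as.numeric(unlist(r$offsets))
      r$heights <- as.numeric(unlist(r$heights))
      r$center <- as.numeric(r$center)
      r$fwhm <- as.numeric(r$fwhm)
      r$protons <- as.numeric(r$protons)
      r
    })
    m
  })
  class(lib) <- "peak_library"
  validate_peak_library(lib)
  lib
}

validate_peak_library <- function(lib) {
  nms <- vapply(lib$metabolites, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("peak library: duplicate metabolite names")
  has_anchor <- FALSE
  for (m in lib$metabolites) {
    for (r in m$resonances) {
      shifts <- r$center + r$offsets
      if (any(shifts < 0 | shifts > 10))
        stop("peak library: shift outside [0, 10] ppm for ", m$name)
      if (any(r$heights <= 0) || abs(sum(r$heights) - 1) > 1e-8)
        stop("peak library: line heights of ", m$name,
             " must be positive and sum to 1")
      if (m$name == "glucose" && abs(r$center - 5.233) < 1e-9) has_anchor <- TRUE
    }
  }
  if (!has_anchor)
    stop("peak library: missing glucose anchor resonance at 5.233 ppm")
  invisible(lib)
}

peak_library_names <- function(lib) {
  vapply(lib$metabolites, `[[`, "", "name")
}

#' Map spectral buckets to metabolites
#'
#' Assigns the included buckets of a bucket specification to metabolites:
#' every bucket whose span overlaps a resonance line's core
#' (`center +/- line_widths * FWHM`) belongs to that line's metabolite, so
#' a multiplet typically claims two or three adjacent buckets ("duplicate"
#' buckets, deduplicated downstream by [select_candidates()]). Buckets not
#' touched by any library line are left unassigned and surface as unknown
#' variables. Where two metabolites claim the same bucket, the larger
#' expected line area (proton weight x relative height) wins.
#'
#' @param library a [load_peak_library()] object.
#' @param spec a [bucket_spec()].
#' @param line_widths half-width of a line's claimed core, in FWHM units.
#' @return data frame `bucket` (center shift), `metabolite`.
#' @export
bucket_metabolite_map <- function(library, spec, line_widths = 1) {
  spans <- bucket_spans(spec)
  spans <- spans[!spans$excluded, ]
  out <- data.frame(bucket = numeric(0), metabolite = character(0),
                    weight = numeric(0), stringsAsFactors = FALSE)
  for (m in library$metabolites) {
    for (r in m$resonances) {
      shifts <- r$center + r$offsets
      for (k in seq_along(shifts)) {
        lo <- shifts[k] - line_widths * r$fwhm
        hi <- shifts[k] + line_widths * r$fwhm
        i <- which(spans$low < hi & spans$high > lo)
        if (length(i)) {
          out <- rbind(out, data.frame(
            bucket = spans$center[i], metabolite = m$name,
            weight = r$protons * r$heights[k], stringsAsFactors = FALSE))
        }
      }
    }
  }
  # resolve collisions by expected area
  out <- out[order(out$bucket, -out$weight), ]
  out <- out[!duplicated(out$bucket), c("bucket", "metabolite")]
  rownames(out) <- NULL
  out
}
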