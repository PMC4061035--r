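#' Bucket specification
#'
#' Fixed-width spectral binning ("bucketing") over 9.0-0.5 ppm in 0.01 ppm
#' steps, with seven default exclusion windows: the urea region
#' (6.00-5.60 ppm), residual water (5.20-4.68 ppm), and five EDTA windows
#' (3.63-3.60, 3.23-3.20, 3.15-3.07, 2.70-2.68, 2.58-2.53 ppm). Buckets are
#' half-open `[low, low + width)` intervals anchored at the range start; a
#' bucket is excluded when its span overlaps any window with positive
#' length, which makes the default counts exact: 850 buckets before
#' exclusion, 737 after.
#'
#' @param low,high bucket range in ppm.
#' @param width bucket width in ppm.
#' @param exclusions two-column matrix of `[low, high]` windows;
#'   `default_exclusions()` when omitted.
#' @return list of class `"bucket_spec"`.
#' @export
bucket_spec <- function(low = 0.5, high = 9.0, width = 0.01,
                        exclusions = default_exclusions()) {
  stopifnot(width > 0, high > low)
  if (!is.null(exclusions)) {
    exclusions <- matrix(as.numeric(exclusions), ncol = 2)
    # clip windows to the bucket range
    exclusions[, 1] <- pmax(exclusions[, 1], low)
    exclusions[, 2] <- pmin(exclusions[, 2], high)
    exclusions <- exclusions[exclusions[, 2] > exclusions[, 1], , drop = FALSE]
  }
  structure(list(low = low, high = high, width = width,
                 exclusions = exclusions), class = "bucket_spec")
}

#' @rdname bucket_spec
#' @export
default_exclusions <- function() {
  win <- artifact_windows()
  rbind(matrix(c(5.60, 6.00, 4.68, 5.20), ncol = 2, byrow = TRUE), win$edta)
}

#' Enumerate bucket spans
#'
#' @param spec a [bucket_spec()].
#' @return data frame `low`, `high`, `center`, `excluded` for every bucket
#'   of the grid (ascending ppm).
#' @export
bucket_spans <- function(spec) {
  n <- floor((spec$high - spec$low) / spec$width + 1e-9)
  lows <- spec$low + (seq_len(n) - 1) * spec$width
  highs <- lows + spec$width
  excluded <- rep(FALSE, n)
  if (!is.null(spec$exclusions)) {
    for (k in seq_len(nrow(spec$exclusions))) {
      lo <- spec$exclusions[k, 1]; hi <- spec$exclusions[k, 2]
      # positive-length overlap of [low, high) with [lo, hi]
      overlap <- pmin(highs, hi) - pmax(lows, lo)
      excluded <- excluded | (overlap > 1e-9)
    }
  }
  data.frame(low = lows, high = highs, center = lows + spec$width / 2,
             excluded = excluded)
}

#' Reference a spectrum to the glucose anomeric proton
#'
#' Shifts the ppm axis by a constant so that the maximum intensity inside
#' the search window lands exactly on the anchor shift (5.233 ppm, the
#' glucose anomeric doublet). When no peak rises above the noise floor in
#' the window -- e.g. the glucose-free "diseased" outlier samples --
#' referencing is skipped with a warning and the spectrum is returned
#' unshifted.
#'
#' @param spectrum an `"nmr_spectrum"`.
#' @param anchor_shift target shift in ppm.
#' @param search_window `c(low, high)` ppm interval searched for the peak.
#' @param min_snr minimum peak height over the noise floor (median plus
#'   `min_snr` robust SDs of the 9.2-9.5 ppm signal-free region).
#' @return the spectrum with shifted axis; the applied shift is recorded in
#'   `provenance$shift_applied`.
#' @export
reference_spectrum <- function(spectrum, anchor_shift = 5.233,
                               search_window = c(5.205, 5.285), min_snr = 10) {
  ppm <- spectrum$ppm
  if (search_window[1] < min(ppm) || search_window[2] > max(ppm))
    stop("search window outside spectral axis")
  idx <- which(ppm >= search_window[1] & ppm <= search_window[2])
  quiet <- spectrum$intensity[ppm >= 9.2]
  if (!length(quiet)) quiet <- spectrum$intensity
  floor_level <- stats::median(quiet) + min_snr * stats::mad(quiet)
  i <- idx[which.max(spectrum$intensity[idx])]
  if (spectrum$intensity[i] <= floor_level) {
    warning("no reference peak above noise floor in [",
            search_window[1], ", ", search_window[2],
            "] ppm; spectrum returned unshifted")
    spectrum$provenance$shift_applied <- 0
    return(spectrum)
  }
  shift <- anchor_shift - ppm[i]
  spectrum$ppm <- ppm + shift
  spectrum$provenance$shift_applied <- shift
  spectrum
}

# Trapezoid integration of the piecewise-linear spectrum, evaluated through
# its cumulative integral so that bucketing a whole spectrum costs O(points
# + buckets). Interpolation at the bucket bounds makes a flat spectrum
# integrate to exactly height x width, and contiguous buckets partition the
# total integral without double counting.
cum_trapz_at <- function(ppm, y, x) {
  n <- length(ppm)
  cum <- c(0, cumsum(diff(ppm) * (y[-1] + y[-n]) / 2))
  i <- pmin(pmax(findInterval(x, ppm), 1L), n - 1L)
  yx <- y[i] + (y[i + 1] - y[i]) * (x - ppm[i]) / (ppm[i + 1] - ppm[i])
  cum[i] + (x - ppm[i]) * (y[i] + yx) / 2
}

trapz_window <- function(ppm, y, lo, hi) {
  v <- cum_trapz_at(ppm, y, c(lo, hi))
  v[2] - v[1]
}

#' Bucket a spectrum
#'
#' Reduces a spectrum to per-bucket trapezoid integrals over the included
#' buckets of the specification. Accepts ascending or descending ppm axes.
#'
#' @param spectrum an `"nmr_spectrum"`.
#' @param spec a [bucket_spec()].
#' @return named numeric vector of integrals; names are the bucket center
#'   shifts formatted to 4 decimals.
#' @export
bucket_spectrum <- function(spectrum, spec) {
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  if (ppm[1] > ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  if (min(ppm) > spec$low || max(ppm) < spec$high)
    stop("spectrum does not cover the bucket range ",
         spec$low, "-", spec$high, " ppm")
  spans <- bucket_spans(spec)
  spans <- spans[!spans$excluded, ]
  out <- cum_trapz_at(ppm, y, spans$high) - cum_trapz_at(ppm, y, spans$low)
  names(out) <- sprintf("%.4f", spans$center)
  out
}

#' Build a bucket table from a set of spectra
#'
#' @param spectra named list of `"nmr_spectrum"` objects (all sharing the
#'   bucket range).
#' @param spec a [bucket_spec()].
#' @param meta optional data frame of sample metadata with a `sample_id`
#'   column; rows are matched to the spectra.
#' @return object of class `"bucket_table"`: intensity matrix `X` (samples
#'   x buckets), bucket `centers` and `spans`, `meta`, and normalization /
#'   scaling state.
#' @export
build_bucket_table <- function(spectra, spec = bucket_spec(), meta = NULL) {
  rows <- lapply(spectra, bucket_spectrum, spec = spec)
  X <- do.call(rbind, rows)
  ids <- unname(vapply(spectra, `[[`, "", "sample_id"))
  rownames(X) <- ids
  if (!is.null(meta)) {
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  spans <- bucket_spans(spec)
  spans <- spans[!spans$excluded, ]
  structure(list(X = X, centers = spans$center, spans = spans,
                 spec = spec, meta = meta,
                 normalized = FALSE, norm_constant = NA_real_,
                 scaling = "none", col_mean = NULL, col_sd = NULL),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat("<bucket_table>", nrow(x$X), "samples x", ncol(x$X), "buckets;",
      if (x$normalized) sprintf("normalized (total = %g);", x$norm_constant)
      else "raw;", "scaling:", x$scaling, "\n")
  invisible(x)
}

subset_bucket_table <- function(table, keep) {
  table$X <- table$X[keep, , drop = FALSE]
  if (!is.null(table$meta)) table$meta <- table$meta[keep, , drop = FALSE]
  table
}

#' Total-intensity normalization
#'
#' Divides each sample's bucket row by its own total and multiplies by a
#' constant, correcting inter-sample dilution differences. The default
#' constant of 100 puts bucket values on the percent-of-total-intensity
#' scale on which the study's relative concentrations are reported.
#'
#' @param table a `"bucket_table"`.
#' @param scale row-sum after normalization.
#' @return the normalized table.
#' @export
normalize_total <- function(table, scale = 100) {
  totals <- rowSums(table$X)
  if (any(totals <= 0))
    stop("degenerate sample(s) with nonpositive total intensity: ",
         paste(rownames(table$X)[totals <= 0], collapse = ", "))
  table$X <- table$X / totals * scale
  table$normalized <- TRUE
  table$norm_constant <- scale
  table
}

#' Pareto scaling
#'
#' Centers each bucket column and divides by the square root of its sample
#' standard deviation (n - 1), the intermediate between mean-centering and
#' unit-variance scaling that tames the dynamic range of strong signals
#' without blowing up noise buckets. Zero-variance columns are set to zero.
#' Column means and SDs are stored for back-scaling of loadings.
#'
#' @param table a normalized `"bucket_table"` with at least 2 samples.
#' @return the scaled table (`scaling = "pareto"`).
#' @export
pareto_scale <- function(table) {
  if (!table$normalized)
    stop("normalize the table before Pareto scaling")
  if (nrow(table$X) < 2) stop("Pareto scaling needs at least 2 samples")
  mu <- colMeans(table$X)
  sdv <- apply(table$X, 2, stats::sd)
  Xc <- sweep(table$X, 2, mu)
  pos <- sdv > 0
  Xc[, pos] <- sweep(Xc[, pos, drop = FALSE], 2, sqrt(sdv[pos]), "/")
  Xc[, !pos] <- 0
  table$X <- Xc
  table$scaling <- "pareto"
  table$col_mean <- mu
  table$col_sd <- sdv
  table
}

#' Write / read a bucket table (CSV + JSON sidecar)
#'
#' The CSV carries the intensity matrix with a header row of bucket center
#' shifts (4 decimals); the sidecar JSON records spans, exclusions and the
#' normalization/scaling state so a table round-trips bit-exactly.
#'
#' @param table a `"bucket_table"`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_bucket_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$X), table$X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    spec = list(low = table$spec$low, high = table$spec$high,
                width = table$spec$width,
                exclusions = table$spec$exclusions),
    normalized = table$normalized, norm_constant = table$norm_constant,
    scaling = table$scaling, col_mean = table$col_mean, col_sd = table$col_sd,
    meta = table$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_bucket_table
#' @export
read_bucket_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$sample_id
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  excl <- if (is.null(side$spec$exclusions)) NULL else
    matrix(unlist(side$spec$exclusions), ncol = 2)
  spec <- bucket_spec(side$spec$low, side$spec$high, side$spec$width, excl)
  spans <- bucket_spans(spec)
  spans <- spans[!spans$excluded, ]
  meta <- if (is.null(side$meta)) NULL else as.data.frame(side$meta)
  structure(list(X = X, centers = spans$center, spans = spans, spec = spec,
                 meta = meta,
                 normalized = isTRUE(side$normalized),
                 norm_constant = if (is.null(side$norm_constant)) NA_real_
                                 else side$norm_constant,
                 scaling = side$scaling,
                 col_mean = side$col_mean, col_sd = side$col_sd),
            class = "bucket_table")
}
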