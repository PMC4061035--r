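# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so individual files stay fast.

# A minimal two-metabolite peak library written to a temp file, exercising
# the JSON loader without the full packaged panel.
tiny_library_path <- function() {
  lib <- list(
    name = "tiny",
    metabolites = list(
      list(name = "glucose", synonyms = list(),
           resonances = list(list(center = 5.233, offsets = list(0),
                                  heights = list(1), fwhm = 0.003,
                                  protons = 1))),
      list(name = "lactate", synonyms = list(),
           resonances = list(list(center = 1.33,
                                  offsets = list(-0.0068, 0.0068),
                                  heights = list(0.5, 0.5), fwhm = 0.003,
                                  protons = 3)))
    ))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(lib, path, auto_unbox = TRUE, digits = NA)
  path
}

# Deterministic small bucket table: n samples x p buckets with an optional
# two-group mean shift on the first column.
toy_bucket_table <- function(n = 12, p = 6, shift = 0, seed = 42) {
  set.seed(seed)
  X <- matrix(abs(stats::rnorm(n * p, 10, 1)), n, p)
  g <- rep(0:1, length.out = n)
  X[, 1] <- X[, 1] + shift * g
  spec <- bucket_spec(0.5, 0.5 + p * 0.01, 0.01, exclusions = NULL)
  spans <- bucket_spans(spec)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(X) <- ids
  colnames(X) <- sprintf("%.4f", spans$center)
  structure(list(X = X, centers = spans$center, spans = spans, spec = spec,
                 meta = data.frame(sample_id = ids, group = g),
                 normalized = FALSE, norm_constant = NA_real_,
                 scaling = "none", col_mean = NULL, col_sd = NULL),
            class = "bucket_table")
}

# A flat spectrum of constant intensity over a given axis.
flat_spectrum <- function(value = 2, lo = 0, hi = 9.5, points = 4096) {
  ovimetab:::new_spectrum("flat", seq(lo, hi, length.out = points),
                          rep(value, points))
}

# Cheap cohort settings used by the heavier recovery tests: a coarser axis
# is enough because the 0.003 ppm lines stay well resolved at 16k points.
fast_axis <- function() axis_spec(0, 9.5, 16384L)
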