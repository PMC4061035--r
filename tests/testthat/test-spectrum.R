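lib <- load_peak_library()

test_that("peak library fixture satisfies its invariants", {
  nms <- vapply(lib$metabolites, `[[`, "", "name")
  expect_true("glucose" %in% nms)
  expect_true("lactate" %in% nms)
  for (m in lib$metabolites) {
    for (r in m$resonances) {
      expect_true(all(r$center + r$offsets >= 0 & r$center + r$offsets <= 10))
      expect_true(all(r$heights > 0))
      expect_equal(sum(r$heights), 1, tolerance = 1e-8)
    }
  }
  glc <- lib$metabolites[[match("glucose", nms)]]
  expect_true(any(vapply(glc$resonances, function(r)
    abs(r$center - 5.233) < 1e-9, TRUE)))
  # loader also reads external files
  tiny <- load_peak_library(tiny_library_path())
  expect_equal(length(tiny$metabolites), 2)
})

test_that("rendered signal integrates proportionally to concentration", {
  for (conc in c(0.5, 2)) {
    sp <- render_spectrum(c(lactate = conc), lib, noise_sd = 0,
                          baseline_amplitude = 0)
    # total integral over the axis ~ conc x 4 protons (3 + 1)
    total <- sum(diff(rev(sp$ppm)) *
                   (rev(sp$intensity)[-1] + rev(sp$intensity)[-length(sp$intensity)]) / 2)
    expect_equal(total, conc * 4, tolerance = 0.01)
  }
})

test_that("rendering is linear and seed-deterministic", {
  conc <- c(glucose = 0.7, lactate = 0.9)
  a <- render_spectrum(conc, lib, noise_sd = 0, baseline_amplitude = 0)
  b <- render_spectrum(conc * 2, lib, noise_sd = 0, baseline_amplitude = 0)
  expect_equal(b$intensity, 2 * a$intensity, tolerance = 1e-12)
  n1 <- render_spectrum(conc, lib, seed = 99)
  n2 <- render_spectrum(conc, lib, seed = 99)
  expect_identical(n1$intensity, n2$intensity)
})

test_that("a too-coarse axis warns about unresolved linewidths", {
  expect_warning(
    render_spectrum(c(glucose = 1), lib, axis = axis_spec(0, 9.5, 2048),
                    noise_sd = 0),
    "points per narrowest linewidth")
})

test_that("ppm offset moves the glucose anomeric maximum as constructed", {
  sp <- render_spectrum(c(glucose = 1), lib, noise_sd = 0,
                        baseline_amplitude = 0)
  off <- inject_artifacts(sp, lib, edta_amplitude = 0, water_area = 0,
                          urea_area = 0, ppm_offset = 0.02)
  win <- off$ppm > 5.21 & off$ppm < 5.30    # anomeric search region
  peak <- off$ppm[win][which.max(off$intensity[win])]
  expect_equal(peak, 5.253, tolerance = 5e-4)
})

test_that("diseased mode zeroes glucose and scales lactate tenfold", {
  conc <- c(glucose = 0.73, lactate = 0.9)
  sp <- render_spectrum(conc, lib, noise_sd = 0, baseline_amplitude = 0)
  dis <- inject_artifacts(sp, lib, edta_amplitude = 0, water_area = 0,
                          urea_area = 0, outlier_mode = "diseased")
  integral <- function(s, lo, hi) {
    ppm <- rev(s$ppm); y <- rev(s$intensity)
    idx <- ppm >= lo & ppm <= hi
    sum(diff(ppm[idx]) * (y[idx][-1] + y[idx][-sum(idx)]) / 2)
  }
  # anomeric window: glucose gone
  expect_equal(integral(dis, 5.20, 5.27), 0, tolerance = 1e-6)
  # lactate doublet window: 10x the original
  expect_equal(integral(dis, 1.28, 1.38),
               10 * integral(sp, 1.28, 1.38), tolerance = 1e-3)
})

test_that("EDTA injection only changes the five EDTA windows", {
  conc <- c(glucose = 0.73, lactate = 0.9)
  sp <- render_spectrum(conc, lib, noise_sd = 0)
  art <- inject_artifacts(sp, lib, edta_amplitude = 2, water_area = 0,
                          urea_area = 0)
  changed <- which(abs(art$intensity - sp$intensity) > 1e-12)
  win <- artifact_windows()$edta
  in_windows <- rep(FALSE, length(sp$ppm))
  for (k in seq_len(nrow(win)))
    in_windows <- in_windows | (sp$ppm >= win[k, 1] & sp$ppm <= win[k, 2])
  expect_true(all(in_windows[changed]))
  expect_gt(length(changed), 0)
})

test_that("unknown-metabolite mode adds an alien singlet outside exclusions", {
  sp <- render_spectrum(c(glucose = 0.7), lib, noise_sd = 0,
                        baseline_amplitude = 0)
  out <- inject_artifacts(sp, lib, edta_amplitude = 0, water_area = 0,
                          urea_area = 0, outlier_mode = "unknown_metabolite")
  d <- out$intensity - sp$intensity
  peak <- out$ppm[which.max(d)]
  expect_equal(peak, 6.15, tolerance = 5e-4)
})

test_that("spectra round-trip through two-column CSV", {
  sp <- render_spectrum(c(glucose = 1), lib, axis = axis_spec(0, 9.5, 2048),
                        noise_sd = 0) |> suppressWarnings()
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$ppm, sp$ppm)
  expect_equal(back$intensity, sp$intensity)
})

test_that("simulated cohorts are seed-identical end to end", {
  des <- build_design(n_nc = 2, n_nn = 2)
  ax <- fast_axis()
  a <- simulate_cohort(des, seed = 21, axis = ax)
  b <- simulate_cohort(des, seed = 21, axis = ax)
  expect_identical(lapply(a$spectra, `[[`, "intensity"),
                   lapply(b$spectra, `[[`, "intensity"))
  c_ <- simulate_cohort(des, seed = 22, axis = ax)
  expect_false(identical(a$spectra[[1]]$intensity, c_$spectra[[1]]$intensity))
})
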