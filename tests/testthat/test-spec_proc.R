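test_that("region extraction matches a direct grid count and is idempotent", {
  ppm <- seq(0.5, 5.0, length.out = 8000)
  spec <- new_spectrum(ppm, rnorm(8000))
  cut <- extract_region(spec)
  keep <- ppm >= 1.45 & ppm <= 4.80 &
    !(ppm >= 1.95 & ppm <= 2.15) & !(ppm >= 2.73 & ppm <= 2.87)
  expect_equal(length(cut$ppm), sum(keep))
  # identity when nothing is excluded
  full <- extract_region(spec, keep = range(ppm), exclude = list())
  expect_equal(full$intensity, spec$intensity)
  # idempotent
  again <- extract_region(cut)
  expect_equal(again$ppm, cut$ppm)
  # keep entirely inside an exclusion window
  expect_error(extract_region(spec, keep = c(2.0, 2.1)), "no data points")
  # descending input axes are normalized on construction
  rev_spec <- new_spectrum(rev(ppm), rev(seq_along(ppm)))
  expect_equal(rev_spec$ppm, ppm)
})

test_that("mean normalization fixes row means at one and is scale invariant", {
  set.seed(171)
  mat <- new_spectral_matrix(1:50, matrix(runif(200, 1, 5), 4))
  out <- mean_normalize(mat)
  expect_equal(rowMeans(out$intensity), setNames(rep(1, 4), rownames(out$intensity)),
               tolerance = 1e-12)
  scaled <- mat
  scaled$intensity[2, ] <- 10 * scaled$intensity[2, ]
  out2 <- mean_normalize(scaled)
  expect_equal(out2$intensity[2, ], out$intensity[2, ], tolerance = 1e-12)
  const <- new_spectral_matrix(1:5, matrix(3, 1, 5))
  expect_equal(unname(mean_normalize(const)$intensity[1, ]), rep(1, 5))
  neg <- new_spectral_matrix(1:5, matrix(-1, 1, 5))
  expect_error(mean_normalize(neg), "non-positive")
})

test_that("voigt profile integrates to its nominal area", {
  for (pars in list(c(0.02, 0.01), c(0.05, 1e-6), c(0.01, 0.03))) {
    # dense trapezoid over the core plus adaptive quadrature on the smooth
    # Lorentzian tails (a single adaptive pass misses the narrow spike)
    xc <- seq(-2, 2, by = 1e-4)
    yc <- voigt_profile(xc, 0, pars[1], pars[2])
    core <- sum((yc[-1] + yc[-length(yc)]) / 2) * 1e-4
    tail <- 2 * stats::integrate(voigt_profile, 2, 200, center = 0,
                                 sigma = pars[1], gamma = pars[2],
                                 rel.tol = 1e-9)$value
    expect_equal(core + tail, 1, tolerance = 0.002)
  }
})

test_that("peak fitting recovers areas of isolated and overlapping peaks", {
  x <- seq(2.9, 3.2, length.out = 1200)
  # noiseless near-Lorentzian of known area
  y <- 7.5 * voigt_profile(x, 3.05, 1e-4, 0.004)
  fit <- fit_peaks(new_spectrum(x, y),
                   tibble::tibble(metabolite = "m", center = 3.048,
                                  sigma = 0.002, gamma = 0.002))
  expect_equal(fit$peaks$area, 7.5, tolerance = 0.005 * 7.5)
  # two Voigt peaks separated by ~3x width, 1% noise
  set.seed(181)
  width <- 0.004
  y2 <- 4 * voigt_profile(x, 3.03, 0.002, 0.002) +
    2.5 * voigt_profile(x, 3.03 + 3 * width, 0.002, 0.002)
  y2 <- y2 + rnorm(length(x), 0, 0.01 * max(y2))
  fit2 <- fit_peaks(new_spectrum(x, y2),
                    tibble::tibble(metabolite = c("a", "b"),
                                   center = c(3.029, 3.043),
                                   sigma = 0.002, gamma = 0.002))
  expect_equal(fit2$peaks$area, c(4, 2.5), tolerance = 0.05)
  # flat spectrum: areas ~ 0, no error
  flat <- new_spectrum(x, rep(0.5, length(x)))
  fit3 <- fit_peaks(flat, tibble::tibble(metabolite = "m", center = 3.05,
                                         sigma = 0.002, gamma = 0.002))
  expect_lt(abs(fit3$peaks$area), 1e-6)
})

test_that("fitting is invariant to global intensity scaling", {
  set.seed(191)
  x <- seq(3.0, 3.1, length.out = 500)
  y <- 3 * voigt_profile(x, 3.05, 0.002, 0.002) + rnorm(length(x), 0, 0.5)
  guess <- tibble::tibble(metabolite = "m", center = 3.05,
                          sigma = 0.002, gamma = 0.002)
  f1 <- fit_peaks(new_spectrum(x, y), guess)
  f2 <- fit_peaks(new_spectrum(x, 100 * y), guess)
  expect_equal(f2$peaks$area / f1$peaks$area, 100, tolerance = 1e-6)
})

test_that("TSP-referenced quantification follows the proton arithmetic", {
  expect_equal(quantify_area(area = 10, tsp_area = 10, protons = 9,
                             tsp_nmol = 50, mass_mg = 20), 2.5)
  # doubling the mass halves the concentration
  expect_equal(quantify_area(10, 10, 9, 50, 40), 1.25)
  expect_error(quantify_area(10, 10, NA, 50, 20), "proton")
  expect_error(quantify_area(10, 0, 9, 50, 20), "tsp_area")
})

test_that("end-to-end quantification recovers planted concentrations", {
  ds <- generate_dataset(synth_config(n_samples = 4, n_genes = 310,
                                      n_intrinsic = 30, seed = 201))
  q <- quantify_spectrum(ds$quant_spectra[[1]])
  expect_setequal(q$metabolite,
                  c("myoinositol", "taurine", "choline", "gpc", "pcho",
                    "glucose", "creatine", "glycine"))
  truth <- ds$metabolite_truth[1, ]
  rel <- vapply(seq_len(nrow(q)), function(i) {
    tv <- truth[[q$metabolite[i]]]
    abs(q$concentration[i] - tv) / tv
  }, numeric(1))
  expect_lt(max(rel), 0.10)
})
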