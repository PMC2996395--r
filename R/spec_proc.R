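#' Construct a single NMR spectrum
#'
#' @param ppm Strictly monotone chemical-shift axis (ppm).
#' @param intensity Intensity vector, same length as `ppm`.
#' @param sample_id Sample identifier.
#' @param mass_mg Wet tissue mass in mg (needed for quantification).
#' @param tsp_nmol Amount of the TSP reference in nmol.
#' @return A `spectrum` object. Descending axes are reversed to ascending.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = "s1", mass_mg = NA_real_,
                         tsp_nmol = NA_real_) {
  assert_that(length(ppm) == length(intensity), "ppm/intensity length mismatch")
  d <- diff(ppm)
  assert_that(all(d > 0) || all(d < 0), "ppm axis must be strictly monotone")
  if (all(d < 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = sample_id, mass_mg = mass_mg,
                 tsp_nmol = tsp_nmol),
            class = "spectrum")
}

#' Construct a spectral matrix (samples on a shared ppm axis)
#'
#' @param ppm Shared strictly increasing axis.
#' @param intensity Sample x point matrix; rownames are sample ids.
#' @param regions Optional list of kept `(lo, hi)` intervals describing the
#'   (possibly non-continuous) axis.
#' @return A `spectral_matrix` object.
#' @export
new_spectral_matrix <- function(ppm, intensity, regions = NULL) {
  assert_that(is.matrix(intensity), "intensity must be a matrix")
  assert_that(length(ppm) == ncol(intensity), "axis/matrix width mismatch")
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- paste0("s", seq_len(nrow(intensity)))
  }
  structure(list(ppm = as.numeric(ppm), intensity = intensity,
                 regions = regions), class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d spectra x %d points, %.3f-%.3f ppm\n",
              nrow(x$intensity), length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Long-format view of a spectral matrix
#'
#' @param x A `spectral_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `ppm`, `intensity`.
#' @method tidy spectral_matrix
#' @export
tidy.spectral_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$intensity), each = length(x$ppm)),
    ppm = rep(x$ppm, times = nrow(x$intensity)),
    intensity = as.vector(t(x$intensity))
  )
}

#' Restrict a spectrum to an analysis region
#'
#' Keeps points inside `keep` and outside every `exclude` interval. The
#' default reproduces the usual tissue-profiling region 1.45-4.80 ppm with
#' the two broad lipid windows (around 2.05 and 2.8 ppm) deleted, so the
#' resulting axis is non-continuous by design.
#'
#' @param spec A `spectrum` or `spectral_matrix`.
#' @param keep Length-2 interval `(lo, hi)` in ppm.
#' @param exclude List of length-2 intervals removed from `keep`.
#' @return Object of the same class restricted to the selected points.
#' @export
extract_region <- function(spec, keep = c(1.45, 4.80),
                           exclude = lipid_exclusion_windows()) {
  keep <- sort(keep)
  sel_axis <- function(ppm) {
    sel <- ppm >= keep[1] & ppm <= keep[2]
    for (w in exclude) {
      w <- sort(w)
      sel <- sel & !(ppm >= w[1] & ppm <= w[2])
    }
    sel
  }
  if (inherits(spec, "spectrum")) {
    sel <- sel_axis(spec$ppm)
    assert_that(any(sel), "selected region contains no data points")
    spec$ppm <- spec$ppm[sel]
    spec$intensity <- spec$intensity[sel]
    spec
  } else if (inherits(spec, "spectral_matrix")) {
    sel <- sel_axis(spec$ppm)
    assert_that(any(sel), "selected region contains no data points")
    new_spectral_matrix(spec$ppm[sel], spec$intensity[, sel, drop = FALSE],
                        regions = list(keep = keep, exclude = exclude))
  } else {
    stop_mrs("spec must be a spectrum or spectral_matrix")
  }
}

#' Default lipid exclusion windows
#'
#' Intervals (ppm) covering the broad lipid -CH2- resonances centered near
#' 2.05 and 2.8 ppm that are deleted before spectral clustering.
#' @return List of two `(lo, hi)` intervals.
#' @export
lipid_exclusion_windows <- function() list(c(1.95, 2.15), c(2.73, 2.87))

#' Mean-normalize each spectrum
#'
#' Divides every spectrum (row) by its own mean intensity so that all rows
#' have mean 1; this removes overall intensity differences due to sample
#' amount before clustering.
#'
#' @param mat A `spectral_matrix`.
#' @return The normalized `spectral_matrix`.
#' @export
mean_normalize <- function(mat) {
  assert_that(inherits(mat, "spectral_matrix"), "mat must be a spectral_matrix")
  mu <- rowMeans(mat$intensity)
  bad <- which(mu <= 0)
  if (length(bad)) {
    stop_mrs("non-positive mean intensity for sample(s): ",
             paste(rownames(mat$intensity)[bad], collapse = ", "))
  }
  mat$intensity <- mat$intensity / mu
  mat
}

# Humlicek (1982) "w4" rational approximation to the Faddeeva function
# w(z) = exp(-z^2) erfc(-iz); relative accuracy ~1e-4, ample for lineshapes.
# x, y real vectors (y >= 0); returns Re(w(x + iy)).
faddeeva_re <- function(x, y) {
  t <- complex(real = y, imaginary = -x)
  s <- abs(x) + y
  w <- complex(length.out = length(x))
  r1 <- s >= 15
  if (any(r1)) {
    tt <- t[r1]
    w[r1] <- tt * 0.5641896 / (0.5 + tt * tt)
  }
  r2 <- !r1 & s >= 5.5
  if (any(r2)) {
    tt <- t[r2]
    u <- tt * tt
    w[r2] <- tt * (1.410474 + u * 0.5641896) / (0.75 + u * (3 + u))
  }
  r3 <- !r1 & !r2 & (y >= 0.195 * abs(x) - 0.176)
  if (any(r3)) {
    tt <- t[r3]
    w[r3] <- (16.4955 + tt * (20.20933 + tt * (11.96482 +
               tt * (3.778987 + tt * 0.5642236)))) /
             (16.4955 + tt * (38.82363 + tt * (39.27121 +
               tt * (21.69274 + tt * (6.699398 + tt)))))
  }
  r4 <- !r1 & !r2 & !r3
  if (any(r4)) {
    tt <- t[r4]
    u <- tt * tt
    w[r4] <- exp(u) - tt * (36183.31 - u * (3321.9905 - u * (1540.787 -
               u * (219.0313 - u * (35.76683 - u * (1.320522 -
               u * 0.56419)))))) /
             (32066.6 - u * (24322.84 - u * (9022.228 - u * (2186.181 -
               u * (364.2191 - u * (61.57037 - u * (1.841439 - u)))))))
  }
  Re(w)
}

#' Area-normalized Voigt lineshape
#'
#' Convolution of a Lorentzian (half-width at half-maximum `gamma`) with a
#' Gaussian (sd `sigma`), normalized to unit area, evaluated via the real
#' part of the Faddeeva function.
#'
#' @param x Evaluation points (ppm).
#' @param center Peak position (ppm).
#' @param sigma Gaussian sd (> 0).
#' @param gamma Lorentzian HWHM (>= 0).
#' @return Profile values with unit integral over the real line.
#' @export
voigt_profile <- function(x, center, sigma, gamma) {
  assert_that(sigma > 0, "sigma must be > 0")
  assert_that(gamma >= 0, "gamma must be >= 0")
  u <- (x - center) / (sigma * sqrt(2))
  a <- gamma / (sigma * sqrt(2))
  faddeeva_re(u, rep(a, length(u))) / (sigma * sqrt(2 * pi))
}

# Sum of area-parameterized Voigt peaks evaluated on x
voigt_sum <- function(x, centers, sigmas, gammas, areas) {
  out <- numeric(length(x))
  for (i in seq_along(centers)) {
    out <- out + areas[i] * voigt_profile(x, centers[i], sigmas[i], gammas[i])
  }
  out
}

#' Fit a sum of Voigt peaks plus a linear baseline
#'
#' Least-squares fit of `sum_k area_k * Voigt(x; center_k, sigma_k, gamma_k)
#' + a + b*x` to the intensities inside `window`. The fit is separable: for
#' any candidate shape parameters the areas and baseline coefficients are
#' solved linearly, and only centers and (log) widths are optimized
#' numerically (L-BFGS-B). Centers may move at most `center_tol` from their
#' initial guesses.
#'
#' @param spec A `spectrum`.
#' @param peaks Tibble/data.frame of initial guesses with columns
#'   `metabolite`, `center`, and optionally `sigma`, `gamma`.
#' @param window Length-2 ppm interval to fit inside; defaults to the peak
#'   range padded by 0.03 ppm.
#' @param center_tol Maximum center shift allowed (ppm).
#' @param baseline Fit a first-degree polynomial baseline (default TRUE).
#' @param max_iter Optimizer iteration cap.
#' @return A `peak_fit` list: `peaks` (tibble with fitted `center`, `sigma`,
#'   `gamma`, `area`), `baseline` coefficients, `residual_norm`, and
#'   `convergence`.
#' @export
fit_peaks <- function(spec, peaks, window = NULL, center_tol = 0.01,
                      baseline = TRUE, max_iter = 400L) {
  assert_that(inherits(spec, "spectrum"), "spec must be a spectrum")
  peaks <- tibble::as_tibble(peaks)
  if (is.null(peaks$sigma)) peaks$sigma <- 0.0015
  if (is.null(peaks$gamma)) peaks$gamma <- 0.0015
  if (is.null(window)) {
    window <- range(peaks$center) + c(-0.03, 0.03)
  }
  window <- sort(window)
  assert_that(all(peaks$center >= window[1] & peaks$center <= window[2]),
              "window must contain all peak centers")
  sel <- spec$ppm >= window[1] & spec$ppm <= window[2]
  x <- spec$ppm[sel]
  y <- spec$intensity[sel]
  assert_that(length(x) >= 3L * nrow(peaks) + 2L,
              "too few points in window for the requested peaks")

  k <- nrow(peaks)
  # design matrix for the linear (area + baseline) sub-problem
  lin_solve <- function(centers, sigmas, gammas) {
    cols <- lapply(seq_len(k), function(i) {
      voigt_profile(x, centers[i], sigmas[i], gammas[i])
    })
    X <- do.call(cbind, cols)
    if (baseline) X <- cbind(X, 1, x - mean(x))
    fit <- qr.solve(qr(X), y)
    list(coef = fit, resid = y - X %*% fit)
  }
  # theta = (centers, log sigmas, log gammas)
  obj <- function(theta) {
    ctr <- theta[seq_len(k)]
    sg <- exp(theta[k + seq_len(k)])
    gm <- exp(theta[2L * k + seq_len(k)])
    ls <- try(lin_solve(ctr, sg, gm), silent = TRUE)
    if (inherits(ls, "try-error")) return(1e30)
    sum(ls$resid^2)
  }
  theta0 <- c(peaks$center, log(peaks$sigma), log(peaks$gamma))
  lower <- c(peaks$center - center_tol, rep(log(1e-5), k), rep(log(1e-6), k))
  upper <- c(peaks$center + center_tol, rep(log(0.3), k), rep(log(0.3), k))
  parscale <- c(rep(max(center_tol / 2, 1e-4), k), rep(0.2, 2L * k))
  opt <- optim(theta0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = max_iter, parscale = parscale))
  if (opt$convergence != 0 && opt$convergence != 1) {
    # L-BFGS-B line searches can fail on nearly-flat separable objectives;
    # polish with a bounded Nelder-Mead restart from the best point so far
    obj_box <- function(theta) {
      obj(pmin(pmax(theta, lower), upper))
    }
    opt2 <- optim(pmin(pmax(opt$par, lower), upper), obj_box,
                  method = "Nelder-Mead",
                  control = list(maxit = 10L * max_iter,
                                 parscale = parscale))
    opt2$par <- pmin(pmax(opt2$par, lower), upper)
    if (opt2$value <= opt$value) opt <- opt2
  }
  ctr <- opt$par[seq_len(k)]
  sg <- exp(opt$par[k + seq_len(k)])
  gm <- exp(opt$par[2L * k + seq_len(k)])
  ls <- lin_solve(ctr, sg, gm)
  areas <- ls$coef[seq_len(k)]
  if (opt$convergence != 0 && opt$convergence != 1) {
    cond <- structure(
      class = c("mrs_fit_error", "error", "condition"),
      list(message = paste0("peak fit failed to converge (code ",
                            opt$convergence, "); best-so-far parameters ",
                            "attached as `fit`"),
           call = sys.call(-1),
           fit = list(peaks = peaks, centers = ctr, sigmas = sg,
                      gammas = gm, areas = areas)))
    stop(cond)
  }
  out <- peaks
  out$center <- ctr
  out$sigma <- sg
  out$gamma <- gm
  out$area <- as.numeric(areas)
  structure(list(
    peaks = out,
    baseline = if (baseline) ls$coef[k + 1:2] else c(0, 0),
    window = window,
    residual_norm = sqrt(sum(ls$resid^2)),
    convergence = opt$convergence
  ), class = "peak_fit")
}

#' Absolute metabolite concentration from peak and TSP areas
#'
#' TSP-referenced quantification:
#' `c = (A_m / A_TSP) * (9 / n_m) * tsp_nmol / mass_mg`, in micromoles per
#' gram wet tissue (TSP has 9 equivalent protons).
#'
#' @param area Metabolite peak area (same arbitrary units as `tsp_area`).
#' @param tsp_area Area of the TSP reference peak (> 0).
#' @param protons Number of protons contributing to the metabolite peak.
#' @param tsp_nmol nmol of TSP in the rotor.
#' @param mass_mg Sample wet mass in mg.
#' @return Concentration in umol/g.
#' @export
quantify_area <- function(area, tsp_area, protons, tsp_nmol, mass_mg) {
  assert_that(all(tsp_area > 0), "tsp_area must be > 0")
  assert_that(all(mass_mg > 0), "mass_mg must be > 0")
  assert_that(all(!is.na(protons) & protons > 0),
              "proton count missing for a metabolite")
  (area / tsp_area) * (9 / protons) * tsp_nmol / mass_mg
}

#' Quantify the standard metabolite panel in a single-pulse spectrum
#'
#' Fits each quantification window (see [default_peak_table()]) jointly for
#' all catalogued resonances falling inside it, fits the TSP reference peak,
#' and converts the designated quantification peak areas to umol/g via
#' [quantify_area()]. Lactate is catalogued as a nuisance resonance but never
#' quantified (lipid signals overlap it in tissue spectra).
#'
#' @param spec A `spectrum` with `mass_mg` and `tsp_nmol` set.
#' @param peak_table Resonance catalogue; defaults to [default_peak_table()].
#' @param center_tol Allowed center shift during fitting (ppm).
#' @return Tibble with one row per quantified metabolite: `metabolite`,
#'   `area`, `protons`, `concentration` (umol/g), `residual_norm`.
#' @export
quantify_spectrum <- function(spec, peak_table = default_peak_table(),
                              center_tol = 0.005) {
  assert_that(is.finite(spec$mass_mg) && spec$mass_mg > 0,
              "spectrum needs mass_mg for quantification")
  assert_that(is.finite(spec$tsp_nmol) && spec$tsp_nmol > 0,
              "spectrum needs tsp_nmol for quantification")
  pt <- tibble::as_tibble(peak_table)
  pt <- pt[pt$center >= min(spec$ppm) & pt$center <= max(spec$ppm), ]
  tsp <- pt[pt$metabolite == "tsp", ]
  assert_that(nrow(tsp) == 1L, "peak table must contain one TSP entry")
  wins <- split(pt, pt$window)
  fits <- lapply(wins, function(w) {
    rng <- range(w$center) + c(-0.025, 0.025)
    fit_peaks(spec, w[, c("metabolite", "center", "sigma", "gamma")],
              window = rng, center_tol = center_tol)
  })
  all_peaks <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    pk <- fits[[nm]]$peaks
    pk$window <- nm
    pk$residual_norm <- fits[[nm]]$residual_norm
    pk
  }))
  all_peaks <- dplyr::left_join(
    all_peaks,
    pt[, c("metabolite", "center", "protons", "quant")] |>
      dplyr::rename(center0 = "center"),
    by = "metabolite"
  )
  # left_join by metabolite duplicates rows when a metabolite has several
  # catalogued resonances; keep the (fitted center, catalogue center) match
  all_peaks <- all_peaks[abs(all_peaks$center - all_peaks$center0) <
                           (center_tol + 1e-9), ]
  tsp_area <- all_peaks$area[all_peaks$metabolite == "tsp"]
  qp <- all_peaks[all_peaks$quant & all_peaks$metabolite != "tsp", ]
  tibble::tibble(
    metabolite = qp$metabolite,
    area = pmax(qp$area, 0),
    protons = qp$protons,
    concentration = quantify_area(pmax(qp$area, 0), tsp_area, qp$protons,
                                  spec$tsp_nmol, spec$mass_mg),
    residual_norm = qp$residual_norm
  )
}

#' Resonance catalogue used for simulation and quantification
#'
#' Literature chemical shifts (ppm) for the quantified tissue metabolites
#' (myo-inositol, taurine, choline, GPC, PCho, glucose, creatine, glycine),
#' the TSP reference, and nuisance resonances (lactate, alanine, glucose ring
#' protons) that crowd the 3.2-3.6 ppm region. `quant` marks the designated
#' quantification resonance of each metabolite; `window` groups resonances
#' that are fitted jointly.
#'
#' @return Tibble with columns `metabolite`, `center`, `protons`, `quant`,
#'   `window`, `sigma`, `gamma`.
#' @export
default_peak_table <- function() {
  pk <- function(met, ctr, pr, quant, win) {
    tibble::tibble(metabolite = met, center = ctr, protons = pr,
                   quant = quant, window = win)
  }
  out <- dplyr::bind_rows(
    pk("tsp", 0.00, 9, TRUE, "tsp"),
    pk("creatine", 3.03, 3, TRUE, "creatine"),
    pk("creatine2", 3.93, 2, FALSE, "creatine_ch2"),
    pk("choline", 3.21, 9, TRUE, "choline"),
    pk("pcho", 3.22, 9, TRUE, "choline"),
    pk("gpc", 3.23, 9, TRUE, "choline"),
    pk("taurine_nch2", 3.25, 2, FALSE, "choline"),
    pk("glucose_h2", 3.24, 1, FALSE, "choline"),
    pk("myoinositol_h5", 3.28, 1, FALSE, "choline"),
    pk("taurine", 3.43, 2, TRUE, "taurine"),
    pk("glucose_h4", 3.40, 1, FALSE, "taurine"),
    pk("glucose_h3", 3.46, 1, FALSE, "taurine"),
    pk("myoinositol_h13", 3.53, 2, FALSE, "glycine"),
    pk("glycine", 3.55, 2, TRUE, "glycine"),
    pk("myoinositol_h46", 3.61, 2, FALSE, "glycine"),
    pk("glucose_h6", 3.72, 1, FALSE, "glucose_ring"),
    pk("glucose_h5", 3.84, 1, FALSE, "glucose_ring"),
    pk("myoinositol", 4.06, 1, TRUE, "myoinositol"),
    pk("lactate_ch", 4.11, 1, FALSE, "myoinositol"),
    pk("glucose", 4.64, 1, TRUE, "glucose"),
    pk("lactate", 1.33, 3, FALSE, "lactate"),
    pk("alanine", 1.48, 3, FALSE, "lactate")
  )
  out$sigma <- 0.0012
  out$gamma <- 0.0012
  out
}

# map nuisance resonance rows to the metabolite whose concentration drives
# their area in the simulator
resonance_parent <- function(metabolite) {
  sub("_(h[0-9a-z]+|nch2|ch|ch2)$", "", sub("^creatine2$", "creatine",
      sub("^myoinositol_h(13|46|5)$", "myoinositol", metabolite)))
}
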