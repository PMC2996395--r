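#' Configuration for the synthetic paired-cohort generator
#'
#' Bundles and validates every knob of [generate_dataset()]. Defaults emulate
#' a 46-patient ER-enriched invasive-ductal-carcinoma cohort: a luminal-A
#' dominated subtype mixture, three metabolic subgroups within luminal A (one
#' with the low-glucose / high-alanine Warburg-like signature, one with low
#' myo-inositol and high lipid), a planted cell-cycle-like gene set shifted in
#' the Warburg-like subgroup, and one block of transcripts correlated to
#' myo-inositol concentration.
#'
#' @param n_samples Number of tumor samples.
#' @param n_genes Total number of gene symbols on the (synthetic) array.
#' @param n_intrinsic Number of intrinsic genes carrying subtype centroids.
#' @param subtype_mixture Named proportions over the five intrinsic subtypes
#'   (luminal A/B, basal-like, ERBB2, normal-like); normalized to sum to 1.
#' @param n_metabolic_subgroups Number of metabolic subgroups planted within
#'   luminal A.
#' @param subgroup_effects List (one element per subgroup, named by subgroup
#'   id) of named numeric vectors metabolite -> log2 concentration offset;
#'   the pseudo-metabolite `"lipid"` scales the broad lipid resonances.
#' @param planted_sets List of gene-set plants, each a list with `id`, `size`,
#'   `shift` (log2 units) and `subgroup` (target metabolic subgroup).
#' @param metab_gene_links List of metabolite-transcript links, each a list
#'   with `metabolite`, `n_genes` and `rho` (latent Gaussian correlation in
#'   `[-1, 1]`). Pseudo-metabolites `"lipid"`, `"mm_low"`, `"mm_mid"` and
#'   `"mm_high"` in `subgroup_effects` scale the broad envelope components
#'   below 1.45 ppm and in the 1.5-2.4, 2.45-3.3 and 3.4-4.4 ppm bands.
#' @param ppm_grid Named vector `c(lo, hi, n)` for the shared ppm axis.
#' @param noise_sd Additive spectral noise sd (intensity units).
#' @param conc_sd Per-sample biological log2 sd of metabolite concentrations.
#' @param hump_sd Per-sample log2 sd of the broad lipid/macromolecule
#'   envelope component amplitudes.
#' @param expr_noise_sd Residual sd of intrinsic-gene expression around its
#'   centroid value (log2 units).
#' @param missing_rate Fraction of probe signals set missing completely at
#'   random in the raw arrays.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_samples = 46L,
                         n_genes = 2000L,
                         n_intrinsic = 300L,
                         subtype_mixture = c(lumA = 36, lumB = 1, basal = 1,
                                             erbb2 = 1, normal = 7),
                         n_metabolic_subgroups = 3L,
                         subgroup_effects = list(
                           `1` = c(myoinositol = -0.8, lipid = 0.8,
                                   mm_low = 1.0, mm_mid = -0.6,
                                   mm_high = -0.5),
                           `2` = c(glucose = -1.5, alanine = 1.5,
                                   lactate = 1.0, mm_low = -0.4,
                                   mm_mid = 0.6, mm_high = -0.5),
                           `3` = c(mm_mid = -0.4, mm_high = 0.6)),
                         planted_sets = list(list(id = "cell_cycle_like",
                                                  size = 50L, shift = 1.0,
                                                  subgroup = 2L)),
                         metab_gene_links = list(list(metabolite = "myoinositol",
                                                      n_genes = 30L,
                                                      rho = 0.7)),
                         ppm_grid = c(lo = 0.5, hi = 5.0, n = 8000L),
                         noise_sd = 5,
                         conc_sd = 0.25,
                         hump_sd = 0.12,
                         expr_noise_sd = 0.5,
                         missing_rate = 0.02,
                         seed = 1L) {
  assert_that(n_samples >= 4L, "n_samples must be >= 4")
  assert_that(n_genes > n_intrinsic, "n_genes must exceed n_intrinsic")
  assert_that(length(subtype_mixture) == 5L && !is.null(names(subtype_mixture)),
              "subtype_mixture must be a named length-5 vector")
  assert_that(all(subtype_mixture >= 0) && sum(subtype_mixture) > 0,
              "subtype_mixture must be non-negative and non-degenerate")
  assert_that(ppm_grid[["n"]] >= 2, "ppm grid needs at least 2 points")
  assert_that(ppm_grid[["hi"]] > ppm_grid[["lo"]], "invalid ppm grid bounds")
  for (l in metab_gene_links) {
    assert_that(abs(l$rho) <= 1, "link correlations must lie in [-1, 1]")
  }
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  mixture <- subtype_mixture / sum(subtype_mixture)
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_intrinsic = as.integer(n_intrinsic), subtype_mixture = mixture,
    n_metabolic_subgroups = as.integer(n_metabolic_subgroups),
    subgroup_effects = subgroup_effects, planted_sets = planted_sets,
    metab_gene_links = metab_gene_links, ppm_grid = ppm_grid,
    noise_sd = noise_sd, conc_sd = conc_sd, hump_sd = hump_sd,
    expr_noise_sd = expr_noise_sd,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "synth_config")
}

# typical breast tumor tissue concentrations, umol/g wet weight
baseline_concentrations <- function() {
  c(glucose = 2.0, lactate = 6.0, creatine = 2.0, myoinositol = 3.0,
    taurine = 5.0, glycine = 2.0, choline = 0.4, pcho = 1.0, gpc = 1.0,
    alanine = 1.0)
}

# Broad lipid/macromolecule envelope components (center ppm, Gaussian sd,
# reference amplitude). These carry the smooth baseline structure that makes
# tissue spectra rank-correlate strongly between samples; subgroup
# signatures act on the three in-region bands (mm_low / mm_mid / mm_high).
macromolecule_humps <- function() {
  h <- rbind(c(0.90, 0.20, 30), c(1.30, 0.25, 45), c(1.60, 0.25, 25),
             c(2.30, 0.28, 20), c(2.50, 0.30, 16), c(2.90, 0.30, 18),
             c(3.20, 0.28, 28), c(3.50, 0.28, 24), c(3.90, 0.30, 20),
             c(4.30, 0.30, 14), c(4.70, 0.25, 10))
  colnames(h) <- c("center", "width", "amplitude")
  h
}

# band selectors for the pseudo-metabolite signature offsets
hump_band <- function() {
  ctr <- macromolecule_humps()[, "center"]
  list(lipid = ctr < 1.45,
       mm_low = ctr >= 1.50 & ctr <= 2.40,
       mm_mid = ctr >= 2.45 & ctr <= 3.30,
       mm_high = ctr >= 3.40 & ctr <= 4.40)
}

# Simulate one spectrum (intensity vector) from metabolite concentrations.
# Peak areas are proportional to concentration * protons; `scale` converts
# nmol-protons to intensity-area units. `hump_log2` holds per-component log2
# multipliers for the broad envelope (length nrow(macromolecule_humps())).
simulate_intensity <- function(ppm, conc, hump_log2 = 0, scale = 1,
                               peak_table = default_peak_table(),
                               tsp_nmol = NA_real_, mass_mg = NA_real_) {
  pt <- peak_table[peak_table$metabolite != "tsp", ]
  parent <- resonance_parent(pt$metabolite)
  known <- parent %in% names(conc)
  pt <- pt[known, ]
  parent <- parent[known]
  amount <- if (is.finite(mass_mg)) conc[parent] * mass_mg else conc[parent]
  areas <- scale * amount * pt$protons
  y <- voigt_sum(ppm, pt$center, pt$sigma, pt$gamma, areas)
  if (is.finite(tsp_nmol)) {
    y <- y + scale * tsp_nmol * 9 *
      voigt_profile(ppm, 0.0, 0.0012, 0.0012)
  }
  h <- macromolecule_humps()
  mass_fac <- if (is.finite(mass_mg)) mass_mg / 18 else 1
  amps <- h[, "amplitude"] * 2^hump_log2 * scale * mass_fac
  for (i in seq_len(nrow(h))) {
    y <- y + amps[i] * exp(-0.5 * ((ppm - h[i, "center"]) / h[i, "width"])^2)
  }
  y
}

#' Generate a complete synthetic paired cohort
#'
#' Produces, deterministically for a given configuration (including its
#' seed): CPMG-like profile spectra and single-pulse quantification spectra
#' with per-subgroup metabolite offsets; a probe-level two-color raw array
#' table with intensity-dependent dye bias, additive background surfaces,
#' duplicate/control/unannotated probes and missing values; the underlying
#' true expression matrix; metabolite concentration truth; subtype, subgroup
#' and affected-probe truth labels; a gene-set collection containing the
#' planted sets; the intrinsic centroid table; and per-sample metadata.
#'
#' @param config A [synth_config()].
#' @return A `synthetic_dataset` list; see the elements described above.
#' @export
generate_dataset <- function(config) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    sample_ids <- sprintf("s%02d", seq_len(n))
    subtypes <- names(cfg$subtype_mixture)
    subtype_truth <- setNames(sample(subtypes, n, replace = TRUE,
                                     prob = cfg$subtype_mixture), sample_ids)
    # metabolic subgroups are planted within luminal A only
    luma <- which(subtype_truth == "lumA")
    subgroup_truth <- setNames(rep(NA_integer_, n), sample_ids)
    if (length(luma) >= cfg$n_metabolic_subgroups) {
      subgroup_truth[luma] <- rep_len(seq_len(cfg$n_metabolic_subgroups),
                                      length(luma))[sample(length(luma))]
    }

    # ---- metabolite concentrations (truth) --------------------------------
    mets <- names(baseline_concentrations())
    bands <- hump_band()
    n_humps <- nrow(macromolecule_humps())
    conc <- matrix(NA_real_, n, length(mets),
                   dimnames = list(sample_ids, mets))
    hump_log2 <- matrix(NA_real_, n, n_humps, dimnames = list(sample_ids, NULL))
    for (i in seq_len(n)) {
      off <- setNames(numeric(length(mets)), mets)
      hoff <- numeric(n_humps)
      sg <- subgroup_truth[i]
      if (!is.na(sg)) {
        eff <- cfg$subgroup_effects[[as.character(sg)]] %||% numeric(0)
        for (m in names(eff)) {
          if (m %in% names(bands)) hoff <- hoff + eff[[m]] * bands[[m]]
          else off[m] <- eff[[m]]
        }
      }
      conc[i, ] <- baseline_concentrations() *
        2^(rnorm(length(mets), 0, cfg$conc_sd) + off)
      hump_log2[i, ] <- rnorm(n_humps, 0, cfg$hump_sd) + hoff
    }

    # ---- spectra ----------------------------------------------------------
    ppm <- seq(cfg$ppm_grid[["lo"]], cfg$ppm_grid[["hi"]],
               length.out = cfg$ppm_grid[["n"]])
    profile <- matrix(NA_real_, n, length(ppm),
                      dimnames = list(sample_ids, NULL))
    mass_mg <- round(runif(n, 8, 27), 1)
    tsp_nmol <- rep(50, n)
    for (i in seq_len(n)) {
      profile[i, ] <- simulate_intensity(ppm, conc[i, ],
                                         hump_log2 = hump_log2[i, ]) +
        rnorm(length(ppm), 0, cfg$noise_sd)
    }
    spectra <- new_spectral_matrix(ppm, profile)
    # single-pulse quantification spectra carry the TSP reference and scale
    # with sample mass
    ppm_q <- seq(-0.2, cfg$ppm_grid[["hi"]], by = diff(ppm[1:2]))
    quant_spectra <- lapply(seq_len(n), function(i) {
      y <- simulate_intensity(ppm_q, conc[i, ], hump_log2 = hump_log2[i, ],
                              tsp_nmol = tsp_nmol[i], mass_mg = mass_mg[i]) +
        rnorm(length(ppm_q), 0, cfg$noise_sd)
      new_spectrum(ppm_q, y, sample_id = sample_ids[i],
                   mass_mg = mass_mg[i], tsp_nmol = tsp_nmol[i])
    })
    names(quant_spectra) <- sample_ids

    # ---- expression truth -------------------------------------------------
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    intrinsic <- sprintf("INT%04d", seq_len(cfg$n_intrinsic))
    genes[seq_len(cfg$n_intrinsic)] <- intrinsic
    centroids <- matrix(rnorm(cfg$n_intrinsic * 5), cfg$n_intrinsic, 5,
                        dimnames = list(intrinsic, subtypes))
    expr <- matrix(rnorm(cfg$n_genes * n, 0, 0.8), cfg$n_genes, n,
                   dimnames = list(genes, sample_ids))
    for (i in seq_len(n)) {
      expr[seq_len(cfg$n_intrinsic), i] <-
        centroids[, subtype_truth[i]] +
        rnorm(cfg$n_intrinsic, 0, cfg$expr_noise_sd)
    }
    free <- setdiff(genes, intrinsic)
    gene_sets <- list()
    set_category <- character(0)
    for (ps in cfg$planted_sets) {
      members <- sample(free, ps$size)
      free <- setdiff(free, members)
      tgt <- which(!is.na(subgroup_truth) & subgroup_truth == ps$subgroup)
      expr[members, tgt] <- expr[members, tgt] + ps$shift
      gene_sets[[ps$id]] <- members
      set_category[ps$id] <- "BP"
    }
    link_truth <- list()
    for (lk in cfg$metab_gene_links) {
      members <- sample(free, lk$n_genes)
      free <- setdiff(free, members)
      z <- as.numeric(scale(log2(conc[, lk$metabolite])))
      for (g in members) {
        expr[g, ] <- lk$rho * z + sqrt(1 - lk$rho^2) * rnorm(n)
      }
      id <- paste0("linked_", lk$metabolite)
      gene_sets[[id]] <- members
      set_category[id] <- "BP"
      link_truth[[lk$metabolite]] <- members
    }
    # decoy sets drawn from the whole gene universe
    for (j in seq_len(20L)) {
      id <- sprintf("random_set_%02d", j)
      gene_sets[[id]] <- sample(genes, sample(20:100, 1))
      set_category[id] <- sample(c("BP", "MF", "CC"), 1)
    }
    attr(gene_sets, "category") <- set_category

    # ---- raw two-color arrays --------------------------------------------
    raw <- simulate_raw_arrays(expr, missing_rate = cfg$missing_rate)

    metadata <- tibble::tibble(
      sample_id = sample_ids,
      er_status = ifelse(subtype_truth %in% c("lumA", "lumB") |
                           (subtype_truth == "normal" & runif(n) < 0.5),
                         "positive", "negative"),
      tumor_pct = round(pmin(pmax(rnorm(n, 25, 18), 0), 80)),
      mass_mg = mass_mg,
      tsp_nmol = tsp_nmol
    )

    structure(list(
      config = cfg,
      spectra = spectra,
      quant_spectra = quant_spectra,
      raw_arrays = raw$table,
      expression_truth = expr,
      metabolite_truth = tibble::as_tibble(conc, rownames = "sample_id"),
      subtype_truth = subtype_truth,
      subgroup_truth = subgroup_truth,
      affected_probes_truth = raw$affected_probes,
      link_truth = link_truth,
      gene_sets = gene_sets,
      centroids = centroids,
      metadata = metadata
    ), class = "synthetic_dataset")
  })
}

# Probe-level two-color table from a true log2-ratio matrix. Adds duplicate
# probes, control probes, unannotated probes, smooth intensity-dependent dye
# bias, additive background surfaces and missing values.
simulate_raw_arrays <- function(expr, missing_rate = 0.02,
                                dup_fraction = 0.05, n_controls = 50L,
                                unannotated_fraction = 0.05) {
  genes <- rownames(expr)
  n <- ncol(expr)
  sample_ids <- colnames(expr)
  dup_genes <- sample(genes, ceiling(dup_fraction * length(genes)))
  probe_gene <- c(genes, dup_genes)
  probe_id <- sprintf("P%05d", seq_along(probe_gene))
  no_symbol <- sample(seq_along(probe_id),
                      ceiling(unannotated_fraction * length(probe_id)))
  symbol <- probe_gene
  symbol[no_symbol] <- NA_character_
  ctrl_id <- sprintf("CTRL%03d", seq_len(n_controls))

  a_probe <- runif(length(probe_id), 8, 14) # typical log2 mean intensity
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    m_true <- expr[probe_gene, j]
    a <- a_probe + rnorm(length(a_probe), 0, 0.2)
    # smooth intensity-dependent dye bias plus additive spatial background
    m_obs <- m_true + 0.08 * (a - 11)^2 - 0.3
    g <- 2^(a - m_obs / 2)
    r <- 2^(a + m_obs / 2)
    idx <- seq_along(probe_id)
    bg_g <- 40 + 25 * sin(2 * pi * idx / length(idx) + j) + 10
    bg_r <- 55 + 20 * cos(2 * pi * idx / length(idx) + j / 2) + 10
    g_fg <- g + bg_g
    r_fg <- r + bg_r
    miss <- runif(length(idx)) < missing_rate
    g_fg[miss] <- NA_real_
    r_fg[miss] <- NA_real_
    ctrl_a <- runif(n_controls, 8, 14)
    rows[[j]] <- tibble::tibble(
      array_id = sample_ids[j],
      probe_id = c(probe_id, ctrl_id),
      gene_symbol = c(symbol, rep(NA_character_, n_controls)),
      red_fg = c(r_fg, 2^ctrl_a + 55),
      green_fg = c(g_fg, 2^ctrl_a + 40),
      red_bg = c(bg_r, rep(55, n_controls)),
      green_bg = c(bg_g, rep(40, n_controls)),
      outlier_flag = c(runif(length(idx)) < 0.01, rep(FALSE, n_controls)),
      control_flag = c(rep(FALSE, length(idx)), rep(TRUE, n_controls))
    )
  }
  affected <- sample(probe_id, max(1L, round(0.01 * length(probe_id))))
  list(table = dplyr::bind_rows(rows), affected_probes = affected)
}

#' Generate a paired HR-MAS-effect study
#'
#' Simulates probe-level log2 expression for `n_pairs` patients, each
#' measured twice (a control arm and an arm subjected to the HR MAS MRS
#' procedure). Pairs share a patient effect whose variance exceeds the
#' within-pair noise, so arrays cluster by patient rather than by arm. A
#' planted fraction of probes carries a log2 offset in the treated arm
#' (by default 70% down, 30% up, echoing the predominance of
#' lower-expressed transcripts after tissue spinning).
#'
#' @param n_pairs Number of sample pairs (>= 2).
#' @param n_probes Number of probes.
#' @param affected_fraction Fraction of probes affected, in `(0, 1)`;
#'   `0` is allowed and plants no effect (null study).
#' @param effect_log2fc Absolute log2 fold change of affected probes.
#' @param between_sd Between-patient sd (log2).
#' @param within_sd Within-pair residual sd (log2).
#' @param prop_down Proportion of affected probes shifted downward.
#' @param seed Integer seed.
#' @return A `paired_study` list: `expr` (probe x array matrix), `pairs`
#'   (tibble with `array_id`, `pair`, `arm`), `affected_probes`,
#'   `direction_truth`.
#' @export
generate_paired_hrmas_study <- function(n_pairs = 18L, n_probes = 2000L,
                                        affected_fraction = 0.03,
                                        effect_log2fc = 0.5,
                                        between_sd = 1, within_sd = 0.3,
                                        prop_down = 0.7, seed = 1L) {
  assert_that(n_pairs >= 2L, "n_pairs must be >= 2")
  assert_that(affected_fraction >= 0 && affected_fraction < 1,
              "affected_fraction must lie in [0, 1)")
  with_seed(seed, {
    probes <- sprintf("P%05d", seq_len(n_probes))
    mu <- rnorm(n_probes, 0, 0.5)
    patient <- matrix(rnorm(n_probes * n_pairs, 0, between_sd),
                      n_probes, n_pairs)
    n_aff <- round(affected_fraction * n_probes)
    affected <- if (n_aff > 0 && effect_log2fc != 0) {
      sample(probes, n_aff)
    } else {
      character(0)
    }
    dir <- setNames(rep(0, n_probes), probes)
    if (length(affected)) {
      down <- sample(affected, round(prop_down * length(affected)))
      dir[affected] <- abs(effect_log2fc)
      dir[down] <- -abs(effect_log2fc)
    }
    ctrl <- mu + patient + matrix(rnorm(n_probes * n_pairs, 0, within_sd),
                                  n_probes, n_pairs)
    hrmas <- mu + patient + dir +
      matrix(rnorm(n_probes * n_pairs, 0, within_sd), n_probes, n_pairs)
    pair_ids <- sprintf("pt%02d", seq_len(n_pairs))
    expr <- cbind(ctrl, hrmas)
    rownames(expr) <- probes
    colnames(expr) <- c(paste0(pair_ids, "_ctrl"), paste0(pair_ids, "_hrmas"))
    pairs <- tibble::tibble(
      array_id = colnames(expr),
      pair = rep(pair_ids, 2L),
      arm = rep(c("control", "hrmas"), each = n_pairs)
    )
    structure(list(expr = expr, pairs = pairs, affected_probes = affected,
                   direction_truth = dir[affected]),
              class = "paired_study")
  })
}
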