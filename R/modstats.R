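#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic step-up false discovery rate adjustment:
#' `adj_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and mapped back to
#' the input order. `NA` values are propagated and excluded from `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p), "p must be numeric")
  ok <- !is.na(p)
  assert_that(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0L) return(out)
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1L) * pp[o]))[ro]
  out[ok] <- adj
  out
}

# Inverse of trigamma by Newton iteration on 1/trigamma (monotone, near-linear).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

# Moment-match a scaled inverse-chi-square prior for gene-wise variances from
# the empirical distribution of log s^2 (digamma/trigamma method).
#   log s_g^2 ~ log s0^2 + log chi^2_{d}/d + log chi^2_{d0}/d0 (independent)
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- mean((z - mean(z))^2) * length(z) / (length(z) - 1) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # sample variances no more dispersed than chi^2 sampling noise: infinite
    # prior df, all variances shrunk to the common value
    d0 <- Inf
    s0_2 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, var_prior = s0_2)
}

new_design <- function(type, groups = NULL, pairs = NULL, arms = NULL) {
  structure(list(type = type, groups = groups, pairs = pairs, arms = arms),
            class = "mrs_design")
}

#' Two-group design for moderated testing
#'
#' @param groups Factor (or coercible) of length `ncol(mat)` with exactly two
#'   levels; the effect reported is `mean(level 2) - mean(level 1)`.
#' @return A design object for [moderated_test()].
#' @export
design_two_group <- function(groups) {
  groups <- as.factor(groups)
  assert_that(nlevels(groups) == 2L, "two-group design needs exactly 2 levels")
  new_design("two_group", groups = droplevels(groups))
}

#' Paired design for moderated testing
#'
#' Each pair must appear exactly twice, once per arm; the test is a one-sample
#' moderated t on the within-pair differences `arm 2 - arm 1`.
#'
#' @param pairs Pair identifiers, length `ncol(mat)`.
#' @param arms Factor with two levels giving the arm of each column.
#' @return A design object for [moderated_test()].
#' @export
design_paired <- function(pairs, arms) {
  arms <- as.factor(arms)
  assert_that(nlevels(arms) == 2L, "paired design needs exactly 2 arms")
  tab <- table(pairs, arms)
  bad <- rownames(tab)[rowSums(tab) != 2L | apply(tab, 1, max) != 1L]
  if (length(bad)) {
    stop_mrs("unpaired or duplicated sample(s) for pair(s): ",
             paste(bad, collapse = ", "))
  }
  new_design("paired", pairs = as.character(pairs), arms = arms)
}

# effect + residual variance per gene for a design; returns list(beta, s2, df,
# v) where var(beta_hat) = v * sigma^2
lm_effects <- function(mat, design) {
  if (design$type == "two_group") {
    g <- design$groups
    i1 <- which(g == levels(g)[1L])
    i2 <- which(g == levels(g)[2L])
    n1 <- length(i1); n2 <- length(i2)
    assert_that(n1 >= 2L && n2 >= 2L, "each group needs >= 2 samples")
    m1 <- rowMeans(mat[, i1, drop = FALSE])
    m2 <- rowMeans(mat[, i2, drop = FALSE])
    ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2L
    list(beta = m2 - m1, s2 = (ss1 + ss2) / df, df = df, v = 1 / n1 + 1 / n2)
  } else if (design$type == "paired") {
    arm <- design$arms
    lev <- levels(arm)
    d <- mat[, arm == lev[2L], drop = FALSE][, order(design$pairs[arm == lev[2L]]), drop = FALSE] -
      mat[, arm == lev[1L], drop = FALSE][, order(design$pairs[arm == lev[1L]]), drop = FALSE]
    n <- ncol(d)
    assert_that(n >= 2L, "paired design needs >= 2 pairs")
    m <- rowMeans(d)
    s2 <- rowSums((d - m)^2) / (n - 1L)
    list(beta = m, s2 = s2, df = n - 1L, v = 1 / n)
  } else {
    stop_mrs("unknown design type")
  }
}

#' Empirical-Bayes moderated t-tests
#'
#' Gene-wise linear model effects with the residual variances shrunk toward a
#' common prior by an inverse-chi-square empirical Bayes model:
#' `s2_tilde = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)`, moderated
#' `t = beta / (s_tilde * sqrt(v))` on `d0 + d_g` degrees of freedom. The
#' prior `(d0, s0^2)` is estimated by moment-matching the distribution of
#' `log s2_g` (digamma/trigamma method). Two-sided p-values are
#' Benjamini-Hochberg adjusted.
#'
#' @param mat Numeric gene x sample matrix (log2 scale).
#' @param design A design from [design_two_group()] or [design_paired()].
#' @param prior_df Optional override of the prior degrees of freedom `d0`:
#'   `0` gives the ordinary t-test, `Inf` the pooled-variance z-like test.
#' @return A `moderated_fit` tibble with one row per gene: `gene`, `log2fc`,
#'   `sigma` (ordinary residual sd), `t`, `p_value`, `fdr`, `df_total`.
#'   The prior estimates are available via [glance()].
#' @export
moderated_test <- function(mat, design, prior_df = NULL) {
  assert_that(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  eff <- lm_effects(mat, design)
  assert_that(eff$df >= 1L, "zero residual degrees of freedom")
  prior <- estimate_variance_prior(eff$s2, eff$df)
  if (!is.null(prior_df)) {
    prior$df_prior <- prior_df
    if (is.infinite(prior_df)) {
      prior$var_prior <- mean(eff$s2)
    } else if (prior_df == 0) {
      prior$var_prior <- NA_real_
    }
  }
  d0 <- prior$df_prior
  if (is.infinite(d0)) {
    s2_post <- rep(prior$var_prior, length(eff$s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- eff$s2
    df_total <- eff$df
  } else {
    s2_post <- (d0 * prior$var_prior + eff$df * eff$s2) / (d0 + eff$df)
    df_total <- d0 + eff$df
  }
  tstat <- eff$beta / sqrt(s2_post * eff$v)
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * pt(-abs(tstat), df = df_total)
  }
  genes <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  out <- tibble::tibble(
    gene = genes,
    log2fc = unname(eff$beta),
    sigma = unname(sqrt(eff$s2)),
    t = unname(tstat),
    p_value = unname(p),
    fdr = bh_adjust(unname(p)),
    df_total = df_total
  )
  structure(out, class = c("moderated_fit", class(out)),
            df_prior = d0, var_prior = prior$var_prior,
            df_residual = eff$df, design_type = design$type)
}

#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    df_prior = attr(x, "df_prior"),
    var_prior = attr(x, "var_prior"),
    df_residual = attr(x, "df_residual"),
    design = attr(x, "design_type")
  )
}

#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Maxmean gene-set statistic
#'
#' For gene scores `z` restricted to a set S of size m, computes
#' `s_plus = sum(max(z, 0)) / m` and `s_minus = sum(max(-z, 0)) / m` and
#' returns `s_plus` if `s_plus >= s_minus`, else `-s_minus`.
#'
#' @param z Named numeric vector of per-gene scores.
#' @param members Character vector of set member gene ids (or integer indices).
#' @return Signed maxmean statistic (length-1 numeric).
#' @export
maxmean_statistic <- function(z, members) {
  zi <- if (is.character(members)) z[intersect(members, names(z))] else z[members]
  zi <- zi[!is.na(zi)]
  assert_that(length(zi) > 0L, "gene set has empty intersection with scores")
  m <- length(zi)
  s_plus <- sum(pmax(zi, 0)) / m
  s_minus <- sum(pmax(-zi, 0)) / m
  if (s_plus >= s_minus) s_plus else -s_minus
}

# maxmean for many sets at once given an indicator matrix (sets x genes) and a
# score matrix (genes x permutations); returns sets x permutations
maxmean_matrix <- function(ind, zmat, set_sizes) {
  pos <- ind %*% pmax(zmat, 0) / set_sizes
  neg <- ind %*% pmax(-zmat, 0) / set_sizes
  ifelse(pos >= neg, pos, -neg)
}

#' Permutation gene-set analysis with the maxmean statistic
#'
#' Scores each gene with a moderated t between the two groups, summarizes
#' gene sets with the signed maxmean statistic, restandardizes set statistics
#' by the mean and sd of maxmean over random sets of equal size drawn from all
#' genes, and obtains two-sided p-values from sample-label permutations:
#' `p = (1 + #\{|perm| >= |obs|\}) / (n_perm + 1)`. BH-adjusted values across
#' sets are reported alongside raw p-values.
#'
#' The variance-moderation prior `(d0, s0^2)` is estimated once from the
#' observed labels and reused across permutations.
#'
#' @param mat Numeric gene x sample matrix.
#' @param labels Two-level grouping of the columns.
#' @param sets Named list of character vectors of gene ids.
#' @param n_perm Number of label permutations (default 10000).
#' @param n_random_sets Random sets per size used for restandardization.
#' @param seed Integer seed for permutations and random sets.
#' @return A `gsa_result` tibble: `set`, `size`, `maxmean`, `statistic`
#'   (restandardized), `direction`, `p_value`, `fdr`.
#' @export
gsa_test <- function(mat, labels, sets, n_perm = 10000L, n_random_sets = 50L,
                     seed = NULL) {
  labels <- as.factor(labels)
  assert_that(nlevels(labels) == 2L, "labels must have two levels")
  assert_that(min(table(labels)) >= 2L, "both groups need >= 2 samples")
  genes <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  rownames(mat) <- genes
  sets <- lapply(sets, function(s) intersect(s, genes))
  sizes <- lengths(sets)
  assert_that(all(sizes > 0L), "every set must intersect the gene universe")
  assert_that(all(sizes <= length(genes)), "set larger than gene universe")

  n <- ncol(mat)
  n1 <- sum(labels == levels(labels)[1L])
  design <- design_two_group(labels)
  eff <- lm_effects(mat, design)
  prior <- estimate_variance_prior(eff$s2, eff$df)
  d0 <- prior$df_prior
  s0_2 <- prior$var_prior

  mod_t <- function(i1) {
    # i1: column indices of group 1; vectorized across a permutation matrix
    x1 <- mat[, i1, drop = FALSE]
    x2 <- mat[, -i1, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
    s2 <- ss / eff$df
    s2p <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
      (d0 * s0_2 + eff$df * s2) / (d0 + eff$df)
    (m2 - m1) / sqrt(s2p * eff$v)
  }

  with_seed(seed, {
    perm_idx <- replicate(n_perm, sample.int(n, n1))
    ind <- matrix(0, nrow = length(sets), ncol = length(genes),
                  dimnames = list(names(sets), genes))
    for (i in seq_along(sets)) ind[i, sets[[i]]] <- 1
    # random sets per observed size, shared across permutations
    rand_ind <- lapply(sort(unique(sizes)), function(m) {
      ri <- matrix(0, nrow = n_random_sets, ncol = length(genes))
      for (r in seq_len(n_random_sets)) ri[r, sample.int(length(genes), m)] <- 1
      ri
    })
    names(rand_ind) <- as.character(sort(unique(sizes)))
  })

  z_obs <- mod_t(which(labels == levels(labels)[1L]))
  zmat <- matrix(0, nrow = nrow(mat), ncol = n_perm)
  for (b in seq_len(n_perm)) zmat[, b] <- mod_t(perm_idx[, b])

  restandardize <- function(zcol_mat) {
    # zcol_mat: genes x K score matrix -> sets x K standardized maxmean
    raw <- maxmean_matrix(ind, zcol_mat, sizes)
    std <- raw
    for (m in unique(sizes)) {
      rm_ <- maxmean_matrix(rand_ind[[as.character(m)]], zcol_mat, m)
      mu <- colMeans(rm_)
      sdv <- apply(rm_, 2L, sd)
      sdv[sdv == 0] <- 1
      rows <- which(sizes == m)
      std[rows, ] <- sweep(sweep(raw[rows, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    }
    list(raw = raw, std = std)
  }

  obs <- restandardize(matrix(z_obs, ncol = 1L))
  perm <- restandardize(zmat)
  exceed <- rowSums(abs(perm$std) >= abs(obs$std)[, rep(1L, n_perm), drop = FALSE])
  p <- (1 + exceed) / (n_perm + 1)

  out <- tibble::tibble(
    set = names(sets),
    size = as.integer(sizes),
    maxmean = as.numeric(obs$raw),
    statistic = as.numeric(obs$std),
    direction = ifelse(obs$raw >= 0, levels(labels)[2L], levels(labels)[1L]),
    p_value = p,
    fdr = bh_adjust(p)
  )
  structure(out, class = c("gsa_result", class(out)),
            n_perm = n_perm, seed = seed)
}
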