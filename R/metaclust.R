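#' Spearman dissimilarity between spectra
#'
#' `d(i, j) = 1 - rho_spearman(spectrum_i, spectrum_j)`, a correlation-based
#' dissimilarity in `[0, 2]` that is invariant to any common monotone
#' transform of a spectrum's intensities. Ties receive average ranks.
#'
#' @param mat A `spectral_matrix` or plain sample x point numeric matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
spearman_dissimilarity <- function(mat) {
  x <- if (inherits(mat, "spectral_matrix")) mat$intensity else mat
  assert_that(is.matrix(x) && ncol(x) >= 3L, "need >= 3 points per spectrum")
  const <- apply(x, 1L, function(r) length(unique(r)) == 1L)
  if (any(const)) {
    stop_mrs("constant spectrum (undefined correlation) for sample(s): ",
             paste(rownames(x)[const], collapse = ", "))
  }
  d <- 1 - cor(t(x), method = "spearman")
  diag(d) <- 0
  d
}

#' Complete-linkage clustering with a dendrogram cut
#'
#' Agglomerative hierarchical clustering of a dissimilarity matrix and a cut
#' of the dendrogram at a fixed height. Cluster ids are renumbered by
#' decreasing size, ties broken by the first member's position.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param cut_height Height at which the tree is cut (>= 0).
#' @param linkage Agglomeration method (default `"complete"`).
#' @return A `cluster_result` list: `hclust` (the tree), `cut_height`,
#'   `labels` (tibble `sample_id`, `subgroup`), `dissimilarity`,
#'   `height_sweep` (tibble of cluster counts over candidate cut heights,
#'   to make the choice of height inspectable).
#' @export
hcluster_cut <- function(d, cut_height, linkage = "complete") {
  assert_that(cut_height >= 0, "cut_height must be >= 0")
  dm <- as.matrix(d)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("s", seq_len(nrow(dm)))
  }
  hc <- hclust(stats::as.dist(dm), method = linkage)
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  first_pos <- vapply(names(sizes), function(g) min(which(raw == g)),
                      numeric(1))
  new_ids <- rank(-as.numeric(sizes) + first_pos / (length(raw) + 1),
                  ties.method = "first")
  labels <- setNames(new_ids[match(raw, names(sizes))], names(raw))
  heights <- sort(unique(c(0, hc$height)))
  sweep_tbl <- tibble::tibble(
    height = heights,
    n_clusters = vapply(heights, function(h) length(unique(cutree(hc, h = h))),
                        numeric(1))
  )
  structure(list(
    hclust = hc,
    cut_height = cut_height,
    labels = tibble::tibble(sample_id = names(labels),
                            subgroup = as.integer(labels)),
    dissimilarity = dm,
    height_sweep = sweep_tbl
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(unique(x$labels$subgroup))
  cat(sprintf("<cluster_result> %d samples in %d subgroup(s) at height %.3f\n",
              nrow(x$labels), k, x$cut_height))
  print(table(subgroup = x$labels$subgroup))
  invisible(x)
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Torgerson (classical) MDS. Coordinates are centered at the origin with
#' axes ordered by decreasing eigenvalue.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param k Number of output dimensions (default 2).
#' @return Tibble with `sample_id` and `dim1` .. `dimk` columns.
#' @export
mds_embed <- function(d, k = 2L) {
  dm <- as.matrix(d)
  fit <- cmdscale(stats::as.dist(dm), k = min(k, nrow(dm) - 1L), eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  assert_that(k <= n_pos,
              paste0("k = ", k, " exceeds the number of positive eigenvalues (",
                     n_pos, ")"))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  coords <- sweep(coords, 2L, colMeans(coords))
  out <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(out) <- paste0("dim", seq_len(k))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(dm) %||%
                     as.character(seq_len(nrow(dm)))),
    out
  )
}

#' Point-wise spectral t-tests between two subgroups
#'
#' A two-sample t-test at every ppm point between two groups of spectra,
#' flagged at `p < alpha` with no multiplicity correction (the customary
#' exploratory display threshold for spectral profiles). The direction of
#' each difference is the sign of `mean(g2) - mean(g1)`.
#'
#' @param mat A `spectral_matrix` (or sample x point matrix with an attached
#'   `ppm` attribute).
#' @param labels Grouping vector named by (or aligned to) the spectra.
#' @param pair Length-2 vector naming the two groups to compare.
#' @param alpha Flagging threshold (default 0.001).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A `pointwise_tests` tibble: `ppm`, `mean_g1`, `mean_g2`, `t`,
#'   `p_value`, `significant`, `direction`.
#' @export
pointwise_tests <- function(mat, labels, pair, alpha = 0.001,
                            var_equal = FALSE) {
  x <- if (inherits(mat, "spectral_matrix")) mat$intensity else mat
  ppm <- if (inherits(mat, "spectral_matrix")) mat$ppm else
    attr(mat, "ppm") %||% seq_len(ncol(x))
  if (!is.null(names(labels)) && !is.null(rownames(x))) {
    labels <- labels[rownames(x)]
  }
  assert_that(length(labels) == nrow(x), "labels must match the spectra")
  assert_that(length(pair) == 2L, "pair must name two groups")
  i1 <- which(labels == pair[1L])
  i2 <- which(labels == pair[2L])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop_mrs("both groups need >= 2 spectra (got ", length(i1), " and ",
             length(i2), ")")
  }
  x1 <- x[i1, , drop = FALSE]
  x2 <- x[i2, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2L, var); v2 <- apply(x2, 2L, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * pt(-abs(tstat), df = df)
  out <- tibble::tibble(
    ppm = ppm,
    mean_g1 = m1,
    mean_g2 = m2,
    t = tstat,
    p_value = p,
    significant = p < alpha,
    direction = sign(m2 - m1)
  )
  structure(out, class = c("pointwise_tests", class(out)),
            pair = pair, alpha = alpha)
}
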