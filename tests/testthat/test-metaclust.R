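test_that("spearman dissimilarity matches rank-then-Pearson and its bounds", {
  set.seed(241)
  x <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  d <- spearman_dissimilarity(x)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], 1 - spearman_oracle(x[i, ], x[j, ]),
                 tolerance = 1e-12)
  }
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  # identical rows -> 0, rank-reversed rows -> 2
  y <- rbind(a = 1:10, b = 1:10, c = 10:1)
  dy <- spearman_dissimilarity(y)
  expect_equal(dy["a", "b"], 0)
  expect_equal(dy["a", "c"], 2)
  const <- rbind(a = rep(1, 5), b = 1:5)
  expect_error(spearman_dissimilarity(const), "constant")
})

test_that("dissimilarity is invariant to per-spectrum monotone transforms", {
  set.seed(251)
  x <- matrix(runif(60, 1, 5), 4, 15)
  d1 <- spearman_dissimilarity(x)
  d2 <- spearman_dissimilarity(exp(x))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("dendrogram cuts behave at the boundaries and order by size", {
  set.seed(261)
  x <- matrix(rnorm(8 * 30), 8, dimnames = list(paste0("s", 1:8), NULL))
  d <- spearman_dissimilarity(x)
  all_one <- hcluster_cut(d, cut_height = 3)
  expect_equal(length(unique(all_one$labels$subgroup)), 1L)
  singletons <- hcluster_cut(d, cut_height = 0)
  expect_equal(length(unique(singletons$labels$subgroup)), 8L)
  expect_error(hcluster_cut(d, cut_height = -1), ">= 0")
  # labels are invariant to sample permutation (up to relabeling)
  perm <- sample(8)
  d2 <- d[perm, perm]
  c1 <- hcluster_cut(d, 0.8)
  c2 <- hcluster_cut(d2, 0.8)
  m1 <- setNames(c1$labels$subgroup, c1$labels$sample_id)
  m2 <- setNames(c2$labels$subgroup, c2$labels$sample_id)
  expect_equal(ari(m1[names(m2)], m2), 1)
  # height sweep is reported for inspection
  expect_true(all(c("height", "n_clusters") %in% names(c1$height_sweep)))
})

test_that("planted spectral subgroups are recovered exactly at the cut", {
  ds <- generate_dataset(synth_config(n_samples = 40, n_genes = 320,
                                      n_intrinsic = 40, seed = 271))
  luma <- names(ds$subtype_truth)[ds$subtype_truth == "lumA"]
  spec <- new_spectral_matrix(ds$spectra$ppm,
                              ds$spectra$intensity[luma, , drop = FALSE])
  spec <- mean_normalize(extract_region(spec))
  cl <- hcluster_cut(spearman_dissimilarity(spec), cut_height = 0.39)
  truth <- ds$subgroup_truth[cl$labels$sample_id]
  expect_equal(ari(cl$labels$subgroup, truth), 1)
})

test_that("classical MDS reproduces collinear geometry and centering", {
  pts <- c(0, 1, 3, 7, 12)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", seq_along(pts))
  emb <- mds_embed(d, k = 1)
  rec <- as.matrix(dist(emb$dim1))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_equal(mean(emb$dim1), 0, tolerance = 1e-12)
  suppressWarnings(expect_error(mds_embed(d, k = 4), "eigenvalues"))
})

test_that("MDS separates planted groups better than within-group spread", {
  set.seed(281)
  base <- matrix(rnorm(3 * 40, sd = 2), 3, 40)
  x <- base[rep(1:3, each = 6), ] + matrix(rnorm(18 * 40, 0, 0.4), 18)
  rownames(x) <- paste0("s", 1:18)
  d <- spearman_dissimilarity(x)
  emb <- mds_embed(d, k = 2)
  grp <- rep(1:3, each = 6)
  coords <- as.matrix(emb[, c("dim1", "dim2")])
  dd <- as.matrix(dist(coords))
  within <- dd[outer(grp, grp, "==") & upper.tri(dd)]
  between <- dd[outer(grp, grp, "!=") & upper.tri(dd)]
  expect_lt(mean(within), mean(between))
})

test_that("point-wise tests are calibrated under the null and powered", {
  set.seed(291)
  n_pts <- 4000
  x <- matrix(rnorm(20 * n_pts), 20, dimnames = list(paste0("s", 1:20), NULL))
  labs <- rep(c(1, 2), each = 10)
  pw <- pointwise_tests(x, labs, pair = c(1, 2), alpha = 0.001)
  flagged <- mean(pw$significant)
  expect_lt(flagged, 0.001 + 3 * sqrt(0.001 * 0.999 / n_pts))
  # alpha = 1 flags everything
  pw_all <- pointwise_tests(x, labs, pair = c(1, 2), alpha = 1)
  expect_true(all(pw_all$significant))
  # planted offset of 5 noise sd over a 50-point band
  x2 <- x
  band <- 101:150
  x2[labs == 2, band] <- x2[labs == 2, band] + 5
  pw2 <- pointwise_tests(x2, labs, pair = c(1, 2), alpha = 0.001)
  expect_gte(mean(pw2$significant[band]), 0.9)
  expect_true(all(pw2$direction[band][pw2$significant[band]] == 1))
  expect_error(pointwise_tests(x, labs, pair = c(1, 9)), ">= 2")
})

test_that("null subgroup configurations yield calibrated point-wise flags", {
  cfg <- synth_config(n_samples = 24, n_genes = 320, n_intrinsic = 40,
                      subtype_mixture = c(lumA = 1, lumB = 0, basal = 0,
                                          erbb2 = 0, normal = 0),
                      subgroup_effects = list(`1` = numeric(0),
                                              `2` = numeric(0),
                                              `3` = numeric(0)),
                      seed = 301)
  ds <- generate_dataset(cfg)
  spec <- mean_normalize(extract_region(ds$spectra))
  labels <- ds$subgroup_truth[rownames(spec$intensity)]
  pw <- pointwise_tests(spec, labels, pair = c(1, 2), alpha = 0.001)
  n_pts <- nrow(pw)
  expect_lt(mean(pw$significant), 0.001 + 3 * sqrt(0.001 / n_pts))
})
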