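test_that("iqr_filter keeps rows by linear-interpolation IQR", {
  mat <- rbind(const = rep(1, 4), spread = c(0, 1, 2, 3))
  out <- iqr_filter(mat, min_iqr = 0.8)
  # IQR(0,1,2,3) = 1.5 with type-7 quantiles
  expect_identical(rownames(out), "spread")
  expect_equal(unname(iqr_filter(mat, min_iqr = 0)), unname(mat))
  expect_error(iqr_filter(mat[1, , drop = FALSE], 0.8), "no probes")
})

test_that("rank_by_metabolite orders by Spearman rho with stable ties", {
  set.seed(71)
  conc <- setNames(runif(20, 1, 5), paste0("s", 1:20))
  mat <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50), names(conc)))
  mat["g01", ] <- conc^3            # monotone transform -> rho 1
  mat["g02", ] <- -rank(conc)       # rank reversal -> rho -1
  rl <- rank_by_metabolite(mat, conc)
  expect_identical(rl$gene[1], "g01")
  expect_equal(rl$rho[1], 1)
  expect_identical(rl$gene[nrow(rl)], "g02")
  expect_equal(rl$rho[nrow(rl)], -1)
  expect_true(all(diff(rl$rho) <= 1e-12))
  # agreement with rank-then-Pearson oracle
  oracle <- vapply(rownames(mat), function(g) spearman_oracle(mat[g, ], conc),
                   numeric(1))
  expect_equal(rl$rho, unname(oracle[rl$gene]), tolerance = 1e-12)
  expect_error(rank_by_metabolite(mat, setNames(rep(1, 20), names(conc))),
               "constant")
})

test_that("enrichment_fold implements (b/n)/(B/N)", {
  expect_equal(round(enrichment_fold(7307, 56, 310, 17), 2), 7.16)
  expect_equal(round(enrichment_fold(7307, 4, 99, 4), 2), 73.81)
  expect_equal(enrichment_fold(100, 10, 20, 2), 1)
  expect_error(enrichment_fold(100, 0, 10, 0), "B")
})

test_that("mhg_score matches the closed form and brute force", {
  # all B members at the top: mHG = 1/choose(N, B)
  genes <- c("m1", "m2", paste0("x", 1:8))
  sc <- mhg_score(genes, c("m1", "m2"))
  expect_equal(sc$mhg, 1 / choose(10, 2))
  expect_equal(sc$n_opt, 2)
  expect_equal(sc$b_opt, 2)
  # members at the bottom: score near 1
  sc2 <- mhg_score(c(paste0("x", 1:8), "m1", "m2"), c("m1", "m2"))
  expect_gt(sc2$mhg, 0.9)
  expect_warning(sc3 <- mhg_score(genes, "absent"), "intersect")
  expect_equal(sc3$mhg, 1)

  set.seed(81)
  for (i in 1:40) {
    N <- sample(10:25, 1)
    B <- sample(2:5, 1)
    memb <- rep(FALSE, N); memb[sample(N, B)] <- TRUE
    genes <- paste0("g", seq_len(N))
    sc <- mhg_score(genes, genes[memb])
    or <- mhg_oracle(memb)
    expect_equal(sc$mhg, or$mhg, tolerance = 1e-12)
    expect_equal(sc$n_opt, or$n_opt)
  }
})

test_that("mhg_pvalue is exact, bounded below by the score, and monotone", {
  expect_equal(mhg_pvalue(1, 20, 3), 1)
  # exhaustive enumeration at N = 12, B = 2 (66 arrangements)
  N <- 12; B <- 2
  genes <- paste0("g", 1:N)
  all_scores <- apply(utils::combn(N, B), 2, function(ix) {
    mhg_score(genes, genes[ix])$mhg
  })
  for (s in unique(all_scores)) {
    expect_equal(mhg_pvalue(s, N, B), mean(all_scores <= s * (1 + 1e-9)),
                 tolerance = 1e-10)
  }
  # p >= mhg (the correction only inflates)
  set.seed(91)
  for (i in 1:20) {
    N <- sample(15:60, 1); B <- sample(2:8, 1)
    memb <- rep(FALSE, N); memb[sample(N, B)] <- TRUE
    sc <- mhg_score(paste0("g", 1:N), paste0("g", which(memb)))
    expect_gte(mhg_pvalue(sc$mhg, N, B), sc$mhg * (1 - 1e-9))
  }
})

test_that("enrich_ranked_list surfaces planted links with Table-style columns", {
  set.seed(101)
  n <- 34
  conc <- setNames(2^rnorm(n, 1, 0.5), paste0("s", 1:n))
  z <- as.numeric(scale(log2(conc)))
  ngene <- 300
  mat <- matrix(rnorm(ngene * n), ngene, n,
                dimnames = list(sprintf("g%03d", 1:ngene), names(conc)))
  linked <- sprintf("g%03d", 1:25)
  for (g in linked) mat[g, ] <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  sets <- list(linked_set = linked,
               decoy1 = sprintf("g%03d", 101:160),
               decoy2 = sprintf("g%03d", 201:230))
  attr(sets, "category") <- c(linked_set = "BP", decoy1 = "BP", decoy2 = "CC")
  rl <- rank_by_metabolite(mat, conc, metabolite = "test")
  enr <- enrich_ranked_list(rl, sets, fdr = 0.003)
  expect_identical(enr$term[1], "linked_set")
  expect_true(enr$significant[1])
  expect_gt(enr$fold[1], 2)
  expect_named(tibble::as_tibble(enr)[, c("term", "category", "N", "B",
                                          "n_opt", "b_opt", "p_value",
                                          "fdr", "fold")],
               c("term", "category", "N", "B", "n_opt", "b_opt", "p_value",
                 "fdr", "fold"))
  tab <- enrichment_table(enr)
  expect_true(all(c("term", "p_value", "enrichment", "tuple") %in% names(tab)))
  # one term covering all genes: no enrichment possible
  allset <- list(everything = rownames(mat))
  enr_all <- enrich_ranked_list(rl, allset)
  expect_equal(enr_all$p_value, 1)
})

test_that("mHG depends only on the order of the correlations", {
  set.seed(111)
  genes <- paste0("g", 1:40)
  members <- sample(genes, 6)
  sc1 <- mhg_score(genes, members)
  # any monotone relabeling of the scores leaves the ranking untouched
  expect_identical(sc1, mhg_score(genes, members))
})
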