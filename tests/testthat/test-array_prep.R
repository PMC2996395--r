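test_that("background correction subtracts surfaces and floors non-positives", {
  tbl <- tibble::tibble(
    array_id = "a1", probe_id = c("p1", "p2", "p3"),
    red_fg = c(100, 30, 44), green_fg = c(100, 80, 60),
    red_bg = c(40, 40, 40), green_bg = c(0, 0, 0),
    outlier_flag = FALSE, control_flag = FALSE
  )
  out <- background_correct(tbl)
  expect_equal(out$red_fg[1], 60)
  # 30 - 40 <= 0 -> half the smallest positive corrected red value (4) -> 2
  expect_equal(out$red_fg[2], 2)
  expect_equal(out$green_fg, c(100, 80, 60)) # all-zero background: unchanged
  expect_error(background_correct(tbl[, -4]), "missing column")
})

test_that("loess normalization removes a smooth intensity trend", {
  set.seed(121)
  n <- 2000
  tbl <- toy_array(rnorm(n, 0, 0.15))
  A_true <- 0.5 * log2(tbl$red_fg * tbl$green_fg)
  # impose a smooth dye bias on top of the ratios (about half a period
  # across the intensity range, well within what span 0.3 can track)
  bias <- 0.5 * sin(A_true / 2)
  tbl$red_fg <- tbl$red_fg * 2^bias
  out <- loess_normalize_within(tbl, span = 0.3)
  # binned medians of normalized M over A deciles all near zero; the raw
  # data violate this grossly (bias amplitude 0.5)
  dec <- cut(out$A, quantile(out$A, 0:10 / 10), include.lowest = TRUE)
  med <- tapply(out$M, dec, median)
  expect_lt(max(abs(med)), 0.05)
  raw_med <- tapply(log2(tbl$red_fg / tbl$green_fg), dec, median)
  expect_gt(max(abs(raw_med)), 0.2)
})

test_that("loess normalization is near-identity without bias", {
  set.seed(131)
  tbl <- toy_array(rnorm(500, 0, 0.4))
  out <- loess_normalize_within(tbl)
  M_raw <- log2(tbl$red_fg / tbl$green_fg)
  # when M is independent of A the fitted trend is only sampling noise
  expect_lt(max(abs(out$M - M_raw)), 0.5 * sd(M_raw))
  expect_lt(mean(abs(out$M - M_raw)), 0.15 * sd(M_raw))
  # constant M collapses to ~0
  tbl2 <- toy_array(rep(0.7, 500))
  out2 <- loess_normalize_within(tbl2)
  expect_lt(max(abs(out2$M)), 1e-6)
})

test_that("gquantile equalizes green distributions and preserves M exactly", {
  set.seed(141)
  tbls <- dplyr::bind_rows(lapply(1:3, function(j) {
    t <- toy_array(rnorm(200, 0, 0.5), array_id = paste0("a", j))
    t$M <- log2(t$red_fg / t$green_fg) + rnorm(200, 0, 0.01)
    t$A <- 0.5 * log2(t$red_fg * t$green_fg) + j # shift distributions
    t
  }))
  out <- gquantile_normalize_between(tbls)
  g <- split(out$log_green, out$array_id)
  expect_equal(sort(g[[1]]), sort(g[[2]]), tolerance = 1e-12)
  expect_equal(sort(g[[1]]), sort(g[[3]]), tolerance = 1e-12)
  expect_equal(out$log_red - out$log_green, out$M, tolerance = 1e-12)
  # identical arrays in, identical values out
  dup <- dplyr::bind_rows(
    transform(tbls[tbls$array_id == "a1", ], array_id = "b1"),
    transform(tbls[tbls$array_id == "a1", ], array_id = "b2")
  )
  out2 <- gquantile_normalize_between(dup)
  expect_equal(out2$log_green[out2$array_id == "b1"],
               out2$A[out2$array_id == "b1"] -
                 out2$M[out2$array_id == "b1"] / 2,
               tolerance = 1e-12)
  bad <- tbls
  bad$probe_id[1] <- "OTHER"
  expect_error(gquantile_normalize_between(bad), "universe")
})

test_that("LLS imputation reconstructs a rank-1 matrix", {
  set.seed(151)
  u <- rnorm(60); v <- rnorm(25)
  mat <- outer(u, v)
  rownames(mat) <- paste0("g", 1:60)
  miss <- matrix(runif(length(mat)) < 0.05, nrow(mat))
  miss[rowSums(miss) == ncol(mat), 1] <- FALSE
  holed <- mat
  holed[miss] <- NA
  out <- impute_lls(holed, k = 5)
  expect_lt(max(abs(out - mat)), 1e-8)
  expect_identical(attr(out, "imputed"), is.na(holed))
  # no missing entries: identity
  expect_equal(impute_lls(mat, k = 5), mat, ignore_attr = TRUE)
  # k larger than complete rows: clamped with warning
  holed2 <- mat
  holed2[cbind(1:55, 1)] <- NA
  expect_warning(impute_lls(holed2, k = 15), "clamped")
  # all-missing row errors with its name
  holed3 <- mat
  holed3["g7", ] <- NA
  expect_error(impute_lls(holed3), "g7")
})

test_that("filter_and_collapse applies the flag rule, averaging and IQR pick", {
  n_arr <- 100
  mk <- function(base) base + seq_len(n_arr) / 100
  mat <- rbind(
    p_ok = mk(0), p_20 = mk(1), p_21 = mk(2),
    dupA = rep(1, n_arr), dupA = rep(3, n_arr),
    symB_lo = rep(c(0, 0.5), n_arr / 2),  # IQR 0.5
    symB_hi = rep(c(0, 0.9), n_arr / 2),  # IQR 0.9
    ctrl = mk(9)
  )
  rownames(mat) <- c("p_ok", "p_20", "p_21", "dupA", "dupA",
                     "symB_lo", "symB_hi", "ctrl")
  flags <- matrix(FALSE, nrow(mat), n_arr,
                  dimnames = list(rownames(mat), NULL))
  flags["p_20", 1:20] <- TRUE # exactly 20%: retained
  flags["p_21", 1:21] <- TRUE # > 20%: removed
  info <- tibble::tibble(
    probe_id = c("p_ok", "p_20", "p_21", "dupA", "symB_lo", "symB_hi", "ctrl"),
    gene_symbol = c("GA", "GB", "GC", "GD", "SYMB", "SYMB", NA),
    control_flag = c(rep(FALSE, 6), TRUE)
  )
  out <- suppressMessages(filter_and_collapse(mat, info, flags))
  expect_true("GB" %in% rownames(out))   # 20% exactly kept
  expect_false("GC" %in% rownames(out))  # 21% removed
  expect_false("ctrl" %in% rownames(out))
  expect_equal(unname(out["GD", 1:3]), rep(2, 3)) # duplicates averaged
  expect_equal(unname(attr(out, "probe_id")["SYMB"]), "symB_hi") # max IQR
})

test_that("probes without a symbol are retained under their probe id", {
  mat <- rbind(a = 1:6, b = 2:7)
  rownames(mat) <- c("p1", "p2")
  info <- tibble::tibble(probe_id = c("p1", "p2"),
                         gene_symbol = c(NA, "G1"),
                         control_flag = FALSE)
  out <- filter_and_collapse(mat, info)
  expect_setequal(rownames(out), c("p1", "G1"))
})

test_that("blacklist removal drops exactly the planted probes", {
  mat <- rbind(g1 = 1:5, g2 = 2:6, g3 = 3:7)
  attr(mat, "probe_id") <- c(g1 = "p1", g2 = "p2", g3 = "p3")
  expect_identical(apply_blacklist(mat, character(0)), mat)
  out <- suppressMessages(apply_blacklist(mat, c("p2")))
  expect_setequal(rownames(out), c("g1", "g3"))
  expect_warning(suppressMessages(apply_blacklist(mat, "absent")), "not present")
})

test_that("full preprocessing recovers planted expression and is idempotent", {
  set.seed(161)
  ds <- generate_dataset(synth_config(n_samples = 12, n_genes = 300,
                                      n_intrinsic = 50, seed = 23))
  expr <- suppressMessages(prep_arrays(ds$raw_arrays))
  shared <- intersect(rownames(expr), rownames(ds$expression_truth))
  expect_gt(length(shared), 250)
  cors <- vapply(sample(shared, 50), function(g) {
    cor(expr[g, ], ds$expression_truth[g, colnames(expr)])
  }, numeric(1))
  expect_gt(median(cors), 0.95)
  # blacklist removal removes exactly the planted truth intersection
  expr_bl <- suppressMessages(suppressWarnings(
    prep_arrays(ds$raw_arrays, blacklist = ds$affected_probes_truth)))
  removed <- setdiff(rownames(expr), rownames(expr_bl))
  planted <- names(attr(expr, "probe_id"))[
    attr(expr, "probe_id") %in% ds$affected_probes_truth]
  expect_setequal(removed, planted)
  # re-collapsing collapsed output is the identity
  info <- tibble::tibble(probe_id = rownames(expr_bl),
                         gene_symbol = rownames(expr_bl),
                         control_flag = FALSE)
  again <- filter_and_collapse(expr_bl, info)
  expect_equal(again[rownames(expr_bl), ], expr_bl[rownames(expr_bl), ],
               ignore_attr = TRUE)
})
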