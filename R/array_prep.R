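#' Background-correct a probe-level two-color table
#'
#' Subtracts the per-probe background surface value from the foreground
#' signal in each channel. Corrected values that are not positive are
#' replaced by half the smallest positive corrected value on the same array
#' and channel, keeping the subsequent log transform defined.
#'
#' @param raw Tibble with columns `array_id`, `probe_id`, `red_fg`,
#'   `green_fg`, `red_bg`, `green_bg` (plus any others, carried through).
#' @return The table with `red_fg`/`green_fg` replaced by corrected signals.
#' @export
background_correct <- function(raw) {
  need <- c("array_id", "red_fg", "green_fg", "red_bg", "green_bg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_mrs("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  floor_pos <- function(x) {
    pos <- x[!is.na(x) & x > 0]
    if (length(pos) == 0L) return(x)
    x[!is.na(x) & x <= 0] <- min(pos) / 2
    x
  }
  raw |>
    dplyr::group_by(.data$array_id) |>
    dplyr::mutate(red_fg = floor_pos(.data$red_fg - .data$red_bg),
                  green_fg = floor_pos(.data$green_fg - .data$green_bg)) |>
    dplyr::ungroup()
}

#' Within-array loess normalization of log-ratios
#'
#' Computes `M = log2(R/G)` and `A = log2(R*G)/2` for one array and removes
#' the smooth intensity-dependent trend: `M' = M - loess_fit(M ~ A)`
#' (degree 1, robust family). `A` is preserved.
#'
#' @param array_tbl Background-corrected table for a single array.
#' @param span Loess span (default 0.3).
#' @return The table with added columns `A` and `M` (normalized log-ratio).
#' @export
loess_normalize_within <- function(array_tbl, span = 0.3) {
  assert_that(length(unique(array_tbl$array_id)) == 1L,
              "loess_normalize_within expects a single array")
  use <- if ("control_flag" %in% names(array_tbl)) !array_tbl$control_flag else
    rep(TRUE, nrow(array_tbl))
  M <- log2(array_tbl$red_fg / array_tbl$green_fg)
  A <- 0.5 * log2(array_tbl$red_fg * array_tbl$green_fg)
  ok <- use & is.finite(M) & is.finite(A)
  assert_that(sum(ok) >= 50L, "need >= 50 usable non-control probes")
  fit <- loess(M[ok] ~ A[ok], span = span, degree = 1, family = "symmetric")
  # interpolate the fitted trend onto every probe's A (constant beyond range)
  o <- order(A[ok])
  trend_fun <- stats::approxfun(A[ok][o], fit$fitted[o], rule = 2, ties = mean)
  trend <- rep(0, nrow(array_tbl))
  trend[is.finite(A)] <- trend_fun(A[is.finite(A)])
  out <- array_tbl
  out$A <- A
  out$M <- M - trend
  out
}

#' Green-channel quantile normalization between arrays
#'
#' Maps each array's green log-intensities onto the mean quantile profile of
#' all arrays (so the sorted green vectors become identical across arrays)
#' and applies the same additive log-scale correction to the red channel, so
#' every within-array log-ratio `M` is left unchanged.
#'
#' @param tbl Combined table of all arrays after [loess_normalize_within()],
#'   with columns `array_id`, `probe_id`, `M`, `A`.
#' @return The table with added columns `log_green` and `log_red`
#'   (normalized), `A` updated accordingly, `M` untouched.
#' @export
gquantile_normalize_between <- function(tbl) {
  arrays <- split(seq_len(nrow(tbl)), tbl$array_id)
  assert_that(length(arrays) >= 2L, "need >= 2 arrays")
  universes <- lapply(arrays, function(i) sort(tbl$probe_id[i]))
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]]))) {
    stop_mrs("arrays have different probe universes")
  }
  logG <- tbl$A - tbl$M / 2
  n_probe <- length(arrays[[1]])
  sorted <- vapply(arrays, function(i) {
    g <- logG[i]
    sort(g, na.last = TRUE)
  }, numeric(n_probe))
  target <- rowMeans(sorted, na.rm = TRUE)
  logG_new <- logG
  for (i in arrays) {
    g <- logG[i]
    ok <- !is.na(g)
    r <- rank(g[ok], ties.method = "first")
    gn <- g
    gn[ok] <- target[r]
    logG_new[i] <- gn
  }
  out <- tbl
  out$log_green <- logG_new
  out$log_red <- logG_new + tbl$M
  out$A <- logG_new + tbl$M / 2
  out
}

#' Local least squares imputation of missing values
#'
#' Each missing entry of a row is predicted by least-squares regression of
#' that row on its `k` most correlated complete rows (by absolute Pearson
#' correlation over the target row's observed columns).
#'
#' @param mat Numeric matrix with missing entries.
#' @param k Number of neighbor rows (default 15; clamped with a warning when
#'   fewer complete rows exist).
#' @return The completed matrix, with an `"imputed"` attribute holding the
#'   logical missingness mask.
#' @export
impute_lls <- function(mat, k = 15L) {
  assert_that(k >= 1L, "k must be >= 1")
  miss <- is.na(mat)
  if (!any(miss)) {
    attr(mat, "imputed") <- miss
    return(mat)
  }
  all_missing <- rownames(mat)[rowSums(!miss) == 0L]
  if (length(all_missing)) {
    stop_mrs("row(s) with all entries missing: ",
             paste(head(all_missing, 5L), collapse = ", "))
  }
  complete_rows <- which(rowSums(miss) == 0L)
  assert_that(length(complete_rows) >= 1L, "no complete rows to regress on")
  if (k > length(complete_rows)) {
    warning("k = ", k, " clamped to ", length(complete_rows),
            " complete rows")
    k <- length(complete_rows)
  }
  comp <- mat[complete_rows, , drop = FALSE]
  out <- mat
  for (i in which(rowSums(miss) > 0L)) {
    obs <- which(!miss[i, ])
    mis <- which(miss[i, ])
    target <- mat[i, obs]
    cc <- abs(as.numeric(cor(t(comp[, obs, drop = FALSE]), target)))
    cc[is.na(cc)] <- 0
    nb <- complete_rows[order(cc, decreasing = TRUE)[seq_len(k)]]
    X <- t(mat[nb, obs, drop = FALSE])
    Xfull <- t(mat[nb, mis, drop = FALSE])
    # pivoted QR tolerates collinear neighbor rows (aliased coefs -> 0)
    coef <- qr.coef(qr(cbind(1, X)), target)
    coef[is.na(coef)] <- 0
    out[i, mis] <- as.numeric(cbind(1, Xfull) %*% coef)
  }
  attr(out, "imputed") <- miss
  out
}

#' Filter and collapse a probe-level log-ratio matrix to gene level
#'
#' Removes control probes and probes flagged as outliers on more than
#' `max_flag_fraction` of the arrays (strict inequality), averages duplicate
#' probes (same probe id), then, among probes sharing a gene symbol, keeps
#' the probe with the highest IQR across samples to represent the symbol.
#' Probes without a symbol are retained keyed by probe id.
#'
#' @param mat Probe x array numeric matrix of log-ratios; rownames are probe
#'   ids (duplicates allowed).
#' @param probe_info Tibble with columns `probe_id`, `gene_symbol`,
#'   `control_flag` (one row per probe id, or per probe occurrence).
#' @param flags Logical probe x array matrix of outlier flags aligned to
#'   `mat` rows, or `NULL` for no flag filtering.
#' @param max_flag_fraction Maximum tolerated flagged fraction (default 0.2).
#' @return Gene x sample `ExpressionMatrix` (numeric matrix) with attribute
#'   `"probe_id"`: the representative probe id of each row.
#' @export
filter_and_collapse <- function(mat, probe_info, flags = NULL,
                                max_flag_fraction = 0.2) {
  probe_ids <- rownames(mat)
  assert_that(!is.null(probe_ids), "mat must have probe ids as rownames")
  info <- tibble::as_tibble(probe_info)
  info <- info[!duplicated(info$probe_id), ]
  info <- info[match(unique(probe_ids), info$probe_id), ]

  keep_probe <- unique(probe_ids)
  ctrl <- info$probe_id[which(info$control_flag)]
  keep_probe <- setdiff(keep_probe, ctrl)
  if (!is.null(flags)) {
    frac <- rowMeans(flags, na.rm = TRUE)
    over <- unique(probe_ids[frac > max_flag_fraction])
    n_removed <- length(intersect(keep_probe, over))
    if (n_removed) {
      message(n_removed, " probe(s) flagged on > ",
              round(100 * max_flag_fraction), "% of arrays removed")
    }
    keep_probe <- setdiff(keep_probe, over)
  }
  assert_that(length(keep_probe) > 0L, "no probes left after flag filtering")

  # average duplicate probe measurements
  keep_rows <- which(probe_ids %in% keep_probe)
  avg <- rowsum(mat[keep_rows, , drop = FALSE], probe_ids[keep_rows]) /
    as.vector(table(probe_ids[keep_rows])[sort(unique(probe_ids[keep_rows]))])
  info <- info[match(rownames(avg), info$probe_id), ]

  symbol <- info$gene_symbol
  key <- ifelse(is.na(symbol) | symbol == "", info$probe_id, symbol)
  iqr <- row_iqr(avg)
  ord <- order(key, -iqr)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  out <- avg[sel, , drop = FALSE]
  rownames(out) <- key[sel]
  assert_that(nrow(out) > 0L, "empty expression matrix after collapsing")
  attr(out, "probe_id") <- setNames(info$probe_id[sel], key[sel])
  out
}

#' Remove blacklisted probes from an expression matrix
#'
#' Drops rows whose representative probe id (the `"probe_id"` attribute set
#' by [filter_and_collapse()], falling back to rownames) appears in
#' `blacklist`. Ids absent from the matrix are ignored with a warning.
#'
#' @param mat Expression matrix.
#' @param blacklist Character vector of probe ids.
#' @return The matrix without blacklisted rows.
#' @export
apply_blacklist <- function(mat, blacklist) {
  if (length(blacklist) == 0L) return(mat)
  ids <- attr(mat, "probe_id") %||% setNames(rownames(mat), rownames(mat))
  hit <- names(ids)[ids %in% blacklist]
  absent <- setdiff(blacklist, ids)
  if (length(absent)) {
    warning(length(absent), " blacklist id(s) not present in the matrix")
  }
  message(length(hit), " blacklisted probe(s) removed")
  out <- mat[setdiff(rownames(mat), hit), , drop = FALSE]
  attr(out, "probe_id") <- ids[setdiff(names(ids), hit)]
  out
}

#' Full two-color preprocessing funnel
#'
#' Background subtraction, within-array loess normalization, green-channel
#' quantile normalization between arrays, probe x array matrix assembly,
#' local least squares imputation, flag/control filtering with duplicate and
#' symbol collapsing, and optional blacklist removal. Per-stage record counts
#' are reported via `message()` so the preprocessing funnel is auditable.
#'
#' @param raw Probe-level two-color table (see [background_correct()] for the
#'   required columns; `outlier_flag`, `control_flag`, `gene_symbol`
#'   expected as in the synthetic generator output).
#' @param blacklist Optional character vector of probe ids to remove.
#' @param span Loess span.
#' @param max_flag_fraction Flag-filter threshold.
#' @param k Neighbors for imputation.
#' @return Gene x sample log2-ratio matrix.
#' @export
prep_arrays <- function(raw, blacklist = NULL, span = 0.3,
                        max_flag_fraction = 0.2, k = 15L) {
  bc <- background_correct(raw)
  norm <- bc |>
    dplyr::group_by(.data$array_id) |>
    dplyr::group_split() |>
    purrr::map(loess_normalize_within, span = span) |>
    dplyr::bind_rows() |>
    gquantile_normalize_between()

  arrays <- unique(norm$array_id)
  probes <- norm$probe_id[norm$array_id == arrays[1L]]
  M <- vapply(arrays, function(a) {
    sub <- norm[norm$array_id == a, ]
    sub$M[match(probes, sub$probe_id)]
  }, numeric(length(probes)))
  rownames(M) <- probes
  flags <- vapply(arrays, function(a) {
    sub <- norm[norm$array_id == a, ]
    sub$outlier_flag[match(probes, sub$probe_id)]
  }, logical(length(probes)))
  info <- norm[norm$array_id == arrays[1L],
               c("probe_id", "gene_symbol", "control_flag")]

  message(length(probes), " probes x ", length(arrays), " arrays assembled")
  M <- impute_lls(M, k = k)
  out <- filter_and_collapse(M, info, flags,
                             max_flag_fraction = max_flag_fraction)
  message(nrow(out), " unique genes/probes after collapsing")
  if (!is.null(blacklist)) out <- apply_blacklist(out, blacklist)
  out
}
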