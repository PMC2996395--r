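#' Median-center every gene
#'
#' Subtracts the across-sample median from each row, as required before
#' correlation-to-centroid subtyping.
#'
#' @param mat Gene x sample numeric matrix.
#' @return The centered matrix (every row median 0).
#' @export
median_center_genes <- function(mat) {
  assert_that(ncol(mat) >= 2L, "need >= 2 samples")
  mat - apply(mat, 1L, median, na.rm = TRUE)
}

#' Nearest-centroid intrinsic subtype classification
#'
#' Each sample's expression over the intrinsic genes shared with the
#' centroid table is correlated (Spearman) to every subtype centroid; the
#' sample is assigned the subtype with the highest correlation provided that
#' correlation strictly exceeds `threshold` and the maximum is unique;
#' otherwise the sample is `"unclassified"`. Centroid genes listed in
#' `blacklist` are removed before matching.
#'
#' @param mat Gene x sample matrix (typically gene median centered).
#' @param centroids Gene x subtype numeric matrix of centroid values.
#' @param threshold Minimum correlation for classification (default 0.1,
#'   strict inequality).
#' @param blacklist Optional gene ids removed from the centroids.
#' @return A `subtype_call` tibble: `sample_id`, `label`, `rho_max`,
#'   `n_genes_matched`, and one `rho_<subtype>` column per centroid.
#' @export
classify_subtypes <- function(mat, centroids, threshold = 0.1,
                              blacklist = NULL) {
  assert_that(is.matrix(centroids) && ncol(centroids) >= 2L,
              "centroids must be a matrix with >= 2 subtypes")
  assert_that(!anyDuplicated(rownames(centroids)),
              "duplicate genes in centroid table")
  cg <- setdiff(rownames(centroids), blacklist)
  shared <- intersect(rownames(mat), cg)
  if (length(shared) < 10L) {
    stop_mrs("only ", length(shared),
             " genes shared between matrix and centroids (need >= 10)")
  }
  sub <- mat[shared, , drop = FALSE]
  cen <- centroids[shared, , drop = FALSE]
  rho <- cor(sub, cen, method = "spearman")
  labels <- apply(rho, 1L, function(r) {
    mx <- max(r)
    if (mx > threshold && sum(r == mx) == 1L) colnames(cen)[which.max(r)]
    else "unclassified"
  })
  out <- tibble::tibble(
    sample_id = colnames(mat),
    label = unname(labels),
    rho_max = unname(apply(rho, 1L, max)),
    n_genes_matched = length(shared)
  )
  rho_tbl <- tibble::as_tibble(rho)
  names(rho_tbl) <- paste0("rho_", colnames(cen))
  out <- dplyr::bind_cols(out, rho_tbl)
  structure(out, class = c("subtype_call", class(out)),
            threshold = threshold)
}
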