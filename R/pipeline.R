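#' Strategy 1: metabolic subgrouping within a transcriptional subtype
#'
#' Preprocesses the raw arrays, calls intrinsic subtypes by correlation to
#' the centroids, restricts the spectra to the samples of `target_subtype`
#' with tumor-cell percentage above `min_tumor_pct`, extracts and
#' mean-normalizes the profiling region, clusters the spectra
#' (complete-linkage, Spearman dissimilarity) cut at `cut_height`, runs
#' point-wise spectral t-tests between every pair of subgroups, and tests
#' gene-set enrichment (moderated t + maxmean GSA) between every subgroup
#' pair.
#'
#' @param dataset A `synthetic_dataset` (or a list with the same elements:
#'   `raw_arrays`, `spectra`, `centroids`, `gene_sets`, `metadata`).
#' @param cut_height Dendrogram cut height (required; report the
#'   `height_sweep` of the result to choose it).
#' @param target_subtype Subtype whose samples are subgrouped (default
#'   `"lumA"`).
#' @param min_tumor_pct Minimum tumor-cell percentage (default 5, strict).
#' @param blacklist Probe ids removed during preprocessing.
#' @param alpha Point-wise test threshold.
#' @param n_perm GSA permutations.
#' @param gsa_fdr GSA significance threshold.
#' @param seed Seed for the GSA permutations.
#' @return A `strategy1_report` list: `expression`, `subtype_calls`,
#'   `clusters`, `mds`, `pointwise` (per group pair), `gsa` (per group
#'   pair), `funnel` (record counts per stage).
#' @export
run_strategy1 <- function(dataset, cut_height, target_subtype = "lumA",
                          min_tumor_pct = 5, blacklist = NULL,
                          alpha = 0.001, n_perm = 1000L, gsa_fdr = 0.01,
                          seed = 1L) {
  expr <- prep_arrays(dataset$raw_arrays, blacklist = blacklist)
  calls <- classify_subtypes(median_center_genes(expr), dataset$centroids)
  meta <- dataset$metadata
  selected <- calls$sample_id[calls$label == target_subtype]
  high_tumor <- meta$sample_id[meta$tumor_pct > min_tumor_pct]
  keep <- intersect(intersect(selected, high_tumor),
                    rownames(dataset$spectra$intensity))
  funnel <- tibble::tibble(
    stage = c("samples", paste0("subtype_", target_subtype),
              paste0("tumor_pct_gt_", min_tumor_pct)),
    n = c(nrow(calls), length(selected), length(keep))
  )
  message(paste(sprintf("%s: %d", funnel$stage, funnel$n), collapse = " -> "))

  spec <- new_spectral_matrix(dataset$spectra$ppm,
                              dataset$spectra$intensity[keep, , drop = FALSE])
  spec <- mean_normalize(extract_region(spec))
  d <- spearman_dissimilarity(spec)
  clusters <- hcluster_cut(d, cut_height = cut_height)
  emb <- mds_embed(d, k = 2L)

  groups <- sort(unique(clusters$labels$subgroup))
  if (length(groups) < 2L) {
    warning("fewer than 2 subgroups at cut height ", cut_height,
            "; omitting between-group testing")
    return(structure(list(expression = expr, subtype_calls = calls,
                          clusters = clusters, mds = emb,
                          pointwise = list(), gsa = list(), funnel = funnel),
                     class = "strategy1_report"))
  }
  labels <- setNames(clusters$labels$subgroup, clusters$labels$sample_id)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  pw <- list(); gsa <- list()
  for (pr in pairs) {
    nm <- paste0("g", pr[1L], "_vs_g", pr[2L])
    in_pair <- names(labels)[labels %in% pr]
    if (min(table(labels[in_pair])) < 2L) next
    pw[[nm]] <- pointwise_tests(spec, labels, pair = pr, alpha = alpha)
    sub_expr <- expr[, in_pair, drop = FALSE]
    gsa[[nm]] <- gsa_test(sub_expr, factor(labels[in_pair]),
                          dataset$gene_sets, n_perm = n_perm, seed = seed)
  }
  structure(list(expression = expr, subtype_calls = calls, clusters = clusters,
                 mds = emb, pointwise = pw, gsa = gsa, funnel = funnel,
                 gsa_fdr = gsa_fdr),
            class = "strategy1_report")
}

#' Strategy 2: metabolite-transcript correlation with mHG enrichment
#'
#' Quantifies the metabolite panel from the single-pulse spectra (or accepts
#' a precomputed concentration table), restricts to ER-positive samples with
#' tumor-cell percentage above `min_tumor_pct`, filters probes at
#' `IQR >= min_iqr`, ranks all transcripts by Spearman correlation to each
#' metabolite, and runs mHG enrichment over the gene-set collection per GO
#' category. Also reports the metabolite-metabolite and metabolite-tumor-%
#' Spearman correlation matrix.
#'
#' @param dataset A `synthetic_dataset` (or equivalent list).
#' @param expression Optional preprocessed gene x sample matrix; computed
#'   from `dataset$raw_arrays` when omitted.
#' @param concentrations Optional sample x metabolite tibble (first column
#'   `sample_id`); quantified from `dataset$quant_spectra` when omitted.
#' @param min_tumor_pct Tumor-cell percentage filter (default 5, strict).
#' @param min_iqr Probe variability filter (default 0.8).
#' @param fdr mHG enrichment significance threshold (default 0.003).
#' @param blacklist Probe ids removed during preprocessing.
#' @return A `strategy2_report` list: `concentrations`, `ranked` (per
#'   metabolite), `enrichment` (per metabolite, Table-2-style columns),
#'   `metabolite_correlations`, `funnel`.
#' @export
run_strategy2 <- function(dataset, expression = NULL, concentrations = NULL,
                          min_tumor_pct = 5, min_iqr = 0.8, fdr = 0.003,
                          blacklist = NULL) {
  expr <- expression %||% prep_arrays(dataset$raw_arrays,
                                      blacklist = blacklist)
  if (is.null(concentrations)) {
    conc_rows <- purrr::map(dataset$quant_spectra, function(sp) {
      q <- quantify_spectrum(sp)
      tibble::tibble(sample_id = sp$sample_id,
                     metabolite = q$metabolite,
                     concentration = q$concentration)
    })
    concentrations <- dplyr::bind_rows(conc_rows) |>
      tidyr::pivot_wider(names_from = "metabolite",
                         values_from = "concentration")
  }
  meta <- dataset$metadata
  er_pos <- meta$sample_id[meta$er_status == "positive"]
  high_tumor <- meta$sample_id[meta$tumor_pct > min_tumor_pct]
  keep <- Reduce(intersect, list(er_pos, high_tumor, colnames(expr),
                                 concentrations$sample_id))
  funnel <- tibble::tibble(
    stage = c("samples", "er_positive",
              paste0("tumor_pct_gt_", min_tumor_pct)),
    n = c(ncol(expr), length(intersect(er_pos, colnames(expr))), length(keep))
  )
  message(paste(sprintf("%s: %d", funnel$stage, funnel$n), collapse = " -> "))

  expr_f <- iqr_filter(expr[, keep, drop = FALSE], min_iqr = min_iqr)
  message(nrow(expr_f), " probes with IQR >= ", min_iqr)
  conc <- concentrations[match(keep, concentrations$sample_id), ]
  mets <- setdiff(names(conc), "sample_id")
  ranked <- list(); enr <- list()
  for (m in mets) {
    cv <- setNames(conc[[m]], conc$sample_id)
    ranked[[m]] <- rank_by_metabolite(expr_f, cv, metabolite = m)
    enr[[m]] <- enrich_ranked_list(ranked[[m]], dataset$gene_sets, fdr = fdr)
  }
  # metabolite-metabolite and metabolite-tumor% correlations
  cm <- as.matrix(conc[, mets, drop = FALSE])
  aux <- cbind(log2(cm), tumor_pct = meta$tumor_pct[match(keep,
                                                          meta$sample_id)])
  met_cor <- cor(aux, method = "spearman")
  structure(list(concentrations = conc, ranked = ranked, enrichment = enr,
                 metabolite_correlations = met_cor, funnel = funnel,
                 fdr = fdr),
            class = "strategy2_report")
}

#' Paired HR-MAS-effect study: blacklist construction
#'
#' One-sample moderated t-tests on the within-pair differences
#' (HR MAS arm minus control arm) of a paired study; probes significant at
#' `fdr` form the blacklist, reported with direction counts. Hierarchical
#' clustering of the arrays (correlation dissimilarity) is included to check
#' that samples pair by patient, and an optional paired t-test on RIN values
#' assesses RNA-integrity effects.
#'
#' @param study A `paired_study` from [generate_paired_hrmas_study()] (or a
#'   list with `expr`, `pairs`).
#' @param fdr Blacklist threshold (default 0.01).
#' @param rin Optional data frame / tibble with columns `pair`, `control`,
#'   `hrmas` of RIN values.
#' @return An `hrmas_report` list: `tests` (moderated fit tibble),
#'   `blacklist`, `n_lower`, `n_higher`, `clustering` (hclust), `rin_test`
#'   (htest or NULL).
#' @export
run_hrmas_effect_study <- function(study, fdr = 0.01, rin = NULL) {
  design <- design_paired(study$pairs$pair, study$pairs$arm)
  expr <- study$expr[, study$pairs$array_id, drop = FALSE]
  fit <- moderated_test(expr, design)
  black <- fit$gene[fit$fdr < fdr]
  n_lower <- sum(fit$fdr < fdr & fit$log2fc < 0)
  n_higher <- sum(fit$fdr < fdr & fit$log2fc > 0)
  message(length(black), " probes at fdr < ", fdr, " (", n_lower,
          " lower, ", n_higher, " higher after the procedure)")
  hc <- hclust(stats::as.dist(1 - cor(expr)), method = "complete")
  rin_test <- NULL
  if (!is.null(rin)) {
    diffs <- rin$hrmas - rin$control
    rin_test <- if (stats::sd(diffs) == 0) {
      structure(list(p.value = if (all(diffs == 0)) 1 else 0,
                     estimate = mean(diffs), method = "degenerate paired t"),
                class = "htest")
    } else {
      t.test(rin$hrmas, rin$control, paired = TRUE)
    }
  }
  structure(list(tests = fit, blacklist = black, n_lower = n_lower,
                 n_higher = n_higher, clustering = hc, rin_test = rin_test,
                 fdr = fdr),
            class = "hrmas_report")
}
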