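#' Read a two-column (ppm, intensity) spectrum file
#'
#' Tab-separated with a header row; a descending ppm axis is accepted and
#' reversed internally.
#'
#' @param path File path.
#' @param sample_id Sample identifier (defaults to the file name).
#' @param mass_mg,tsp_nmol Optional quantification metadata.
#' @return A `spectrum`.
#' @export
read_spectrum_tsv <- function(path, sample_id = NULL, mass_mg = NA_real_,
                              tsp_nmol = NA_real_) {
  tab <- utils::read.delim(path, header = TRUE)
  assert_that(ncol(tab) >= 2L, "spectrum file needs (ppm, intensity) columns")
  new_spectrum(tab[[1L]], tab[[2L]],
               sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
               mass_mg = mass_mg, tsp_nmol = tsp_nmol)
}

#' Write a spectrum to a two-column TSV
#'
#' @param spec A `spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  utils::write.table(data.frame(ppm = spec$ppm, intensity = spec$intensity),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`,
#' members. The description field is kept as the `"description"` attribute;
#' if it looks like a GO category tag (`BP`/`MF`/`CC`) it also populates the
#' `"category"` attribute used to scope enrichment FDR.
#'
#' @param path File path.
#' @return Named list of character vectors with `description` and `category`
#'   attributes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
                 character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  cat_tag <- toupper(desc)
  category <- ifelse(cat_tag %in% c("BP", "MF", "CC"), cat_tag, "all")
  attr(sets, "category") <- setNames(category, ids)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors; an optional `category` or
#'   `description` attribute fills the description field.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% attr(sets, "category") %||%
    setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, unname(desc[id]), sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample expression (or centroid) table
#'
#' Tab-separated with a header row; first column holds gene ids.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write a gene x sample matrix to TSV
#'
#' @param mat Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the first (id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
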