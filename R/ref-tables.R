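# Published summary tables from a large (10,375-line) Australian wheat
# breeding panel evaluation, bundled as plain CSV so the package's summary
# operations can be validated against reported statistics without access to
# the restricted line-level data.

ref_path <- function(file) {
  system.file("extdata", file, package = "fieldblup", mustWork = TRUE)
}

#' Bundled reference tables from a large wheat panel evaluation
#'
#' Summary tables reported for a 10,375-line Australian wheat breeding
#' panel: per-trait baseline/genomic model fits (heritabilities,
#' log-likelihoods and the additive variance percentage), fivefold
#' cross-validation accuracies for genomic and QTL prediction, the pairwise
#' genetic correlation matrix (additive upper triangle, residual genetic
#' lower triangle), per-chromosome consensus-map counts, and raw trait
#' means and standard deviations. These serve as fixed inputs for the
#' package's summary statistics, e.g.
#' `correlation_summary(ref_trait_correlations())`.
#'
#' @return A tibble, except `ref_trait_correlations()` which returns the
#'   trait x trait matrix.
#' @name ref_tables
NULL

#' @rdname ref_tables
#' @export
ref_model_fits <- function() {
  readr::read_csv(ref_path("panel_model_fits.csv"), show_col_types = FALSE)
}

#' @rdname ref_tables
#' @export
ref_cv_accuracy <- function() {
  readr::read_csv(ref_path("panel_cv_accuracy.csv"), show_col_types = FALSE)
}

#' @rdname ref_tables
#' @export
ref_trait_correlations <- function() {
  df <- readr::read_csv(ref_path("panel_trait_correlations.csv"),
                        show_col_types = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$trait
  m
}

#' @rdname ref_tables
#' @export
ref_map_summary <- function() {
  readr::read_csv(ref_path("panel_map_summary.csv"), show_col_types = FALSE)
}

#' @rdname ref_tables
#' @export
ref_trait_summary <- function() {
  readr::read_csv(ref_path("panel_trait_summary.csv"), show_col_types = FALSE)
}
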