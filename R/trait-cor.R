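# Additive and residual genetic correlations across traits.

#' Pairwise genetic correlations between traits
#'
#' Correlates the BLUP vectors extracted from per-trait genomic fits:
#' additive genetic values `g_a` give the additive correlation matrix and
#' residual genetic values `g_p` the residual genetic matrix. These are
#' shrinkage-based estimates (correlations of predicted effects), the
#' standard report for large panels where joint multi-trait REML is
#' impractical.
#'
#' @param fits Named list of genomic `panel_fit` objects, one per trait
#'   (names default to the fits' traits).
#' @param min_overlap Minimum shared-line fraction before differing line
#'   sets become an error rather than an intersection with warning.
#' @return A `genetic_cor` object: `additive` and `residual` trait x trait
#'   matrices, `traits`, `n_lines`.
#' @export
genetic_correlations <- function(fits, min_overlap = 0.95) {
  if (inherits(fits, "panel_fit")) fits <- list(fits)
  if (!all(vapply(fits, function(f) inherits(f, "panel_fit") &&
                    f$kind == "genomic", TRUE))) {
    abort("`fits` must be genomic panel_fit objects.",
          class = "fieldblup_input_error")
  }
  traits <- names(fits) %||% vapply(fits, `[[`, "", "trait")
  if (is.null(names(fits))) names(fits) <- traits
  sets <- lapply(fits, function(f) f$blup$line_id)
  shared <- Reduce(intersect, sets)
  frac <- length(shared) / max(lengths(sets))
  if (frac < 1) {
    if (frac < min_overlap) {
      abort(sprintf("line sets overlap only %.0f%%; refusing to correlate.",
                    100 * frac), class = "fieldblup_input_error")
    }
    warn(sprintf("differing line sets; using the %d shared lines.",
                 length(shared)))
  }
  ga <- vapply(fits, function(f)
    f$blup$g_a[match(shared, f$blup$line_id)], numeric(length(shared)))
  gp <- vapply(fits, function(f)
    f$blup$g_p[match(shared, f$blup$line_id)], numeric(length(shared)))
  colnames(ga) <- colnames(gp) <- traits
  structure(list(additive = cor(ga), residual = cor(gp),
                 traits = traits, n_lines = length(shared)),
            class = "genetic_cor")
}

#' Combine a genetic correlation pair into one reporting matrix
#'
#' Additive correlations in the upper triangle, residual genetic in the
#' lower, unit diagonal - the conventional single-table layout.
#'
#' @param x A `genetic_cor` object.
#' @return A trait x trait matrix.
#' @export
combined_correlation_matrix <- function(x) {
  stopifnot(inherits(x, "genetic_cor"))
  out <- x$residual
  out[upper.tri(out)] <- x$additive[upper.tri(x$additive)]
  diag(out) <- 1
  out
}

#' Summarise agreement between additive and residual genetic correlations
#'
#' Over all trait pairs: the Pearson correlation between the paired
#' additive and residual entries, the mean absolute correlation of each
#' measure, and the count of pairs whose two correlations share a sign.
#' Zero entries have no sign; under the default `"lenient"` rule they
#' count as agreeing with anything (`"strict"` requires equal `sign()`),
#' and the rule used is recorded in the output.
#'
#' @param x A `genetic_cor` object, or a combined square matrix with
#'   additive correlations in the upper triangle and residual genetic in
#'   the lower (the conventional published layout).
#' @param zero_sign `"lenient"` or `"strict"`.
#' @return One-row tibble: `n_pairs`, `agreement_cor`,
#'   `mean_abs_additive`, `mean_abs_residual`, `n_same_sign`, `zero_rule`.
#' @export
correlation_summary <- function(x, zero_sign = c("lenient", "strict")) {
  zero_sign <- match.arg(zero_sign)
  if (inherits(x, "genetic_cor")) {
    add <- x$additive[upper.tri(x$additive)]
    res <- x$residual[upper.tri(x$residual)]
    t_count <- length(x$traits)
  } else {
    x <- as.matrix(x)
    if (nrow(x) != ncol(x) || nrow(x) < 3L) {
      abort("need a square matrix over at least 3 traits.",
            class = "fieldblup_input_error")
    }
    add <- x[upper.tri(x)]
    res <- t(x)[upper.tri(x)]
    t_count <- nrow(x)
  }
  same <- if (zero_sign == "lenient") {
    add * res > 0 | add == 0 | res == 0
  } else {
    sign(add) == sign(res)
  }
  tibble(n_pairs = length(add),
         n_traits = t_count,
         agreement_cor = cor(add, res),
         mean_abs_additive = mean(abs(add)),
         mean_abs_residual = mean(abs(res)),
         n_same_sign = sum(same),
         zero_rule = zero_sign)
}

#' @export
print.genetic_cor <- function(x, ...) {
  cat(sprintf("Genetic correlations over %d traits (%d shared lines)\n",
              length(x$traits), x$n_lines))
  cat("additive upper triangle / residual genetic lower triangle:\n")
  print(round(combined_correlation_matrix(x), 2))
  invisible(x)
}
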