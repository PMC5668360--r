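#' Simulate multi-trait genetic effects for a panel
#'
#' Marker effects are drawn iid normal per trait (optionally correlated
#' across traits through a Cholesky factor of the supplied additive
#' correlation matrix) and rescaled so the realised variance of the additive
#' genetic values `g_a = M effects` matches each trait's `polygenic_var`.
#' Optional major QTL receive additional effects with standard deviation
#' `qtl_effect_sd`. Residual genetic values `g_p` are iid normal per line.
#'
#' @param M Complete (no missing) lines x markers genotype matrix.
#' @param trait_specs List of [trait_spec()] objects (or a single one).
#' @param additive_cor Optional trait x trait additive correlation matrix
#'   (positive semi-definite); default identity.
#' @param seed Optional integer seed.
#' @return A `panel_truth` list: `marker_effects` (markers x traits), `g_a`,
#'   `g_p` (lines x traits), `qtl` (list of major-QTL marker names per
#'   trait), `trait_specs`.
#' @export
sim_traits <- function(M, trait_specs, additive_cor = NULL, seed = NULL) {
  validate_marker_matrix(M, allow_missing = FALSE)
  if (inherits(trait_specs, "trait_spec")) trait_specs <- list(trait_specs)
  nt <- length(trait_specs)
  p <- ncol(M)
  n <- nrow(M)
  if (is.null(additive_cor)) additive_cor <- diag(nt)
  if (!isTRUE(all.equal(dim(additive_cor), c(nt, nt))) ||
      !isSymmetric(unname(additive_cor))) {
    abort("`additive_cor` must be a symmetric traits x traits matrix.",
          class = "fieldblup_config_error")
  }
  ev <- eigen(additive_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("`additive_cor` is not positive semi-definite.",
          class = "fieldblup_config_error")
  }
  cf <- chol(additive_cor + diag(1e-10, nt))

  with_seed(seed, {
    eff <- matrix(rnorm(p * nt), p, nt) %*% cf
    g_p <- matrix(0, n, nt)
    qtl <- vector("list", nt)
    for (t in seq_len(nt)) {
      spec <- trait_specs[[t]]
      if (spec$polygenic_var == 0) {
        eff[, t] <- 0
      } else {
        g0 <- M %*% eff[, t]
        s <- sqrt(spec$polygenic_var / max(var(as.vector(g0)), 1e-300))
        eff[, t] <- eff[, t] * s
      }
      if (spec$n_qtl > 0L) {
        # a QTL must segregate: draw among polymorphic markers (maf >= 5%
        # where enough exist, any variation otherwise)
        freq <- colMeans((M + 1) / 2)
        maf <- pmin(freq, 1 - freq)
        cand <- which(maf >= 0.05)
        if (length(cand) < spec$n_qtl) cand <- which(maf > 0)
        if (length(cand) < spec$n_qtl) {
          abort("not enough polymorphic markers for the requested QTL.",
                class = "fieldblup_config_error")
        }
        idx <- cand[sample.int(length(cand), spec$n_qtl)]
        eff[idx, t] <- eff[idx, t] + rnorm(spec$n_qtl, sd = spec$qtl_effect_sd)
        qtl[[t]] <- colnames(M)[idx]
      } else {
        qtl[[t]] <- character()
      }
      if (spec$residual_genetic_var > 0) {
        g_p[, t] <- rnorm(n, sd = sqrt(spec$residual_genetic_var))
      }
    }
    g_a <- M %*% eff
    nm <- vapply(trait_specs, `[[`, "", "name")
    dimnames(eff) <- list(colnames(M), nm)
    dimnames(g_a) <- list(rownames(M), nm)
    dimnames(g_p) <- list(rownames(M), nm)
    names(qtl) <- nm
    structure(list(marker_effects = eff, g_a = g_a, g_p = g_p, qtl = qtl,
                   trait_specs = trait_specs),
              class = "panel_truth")
  })
}
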