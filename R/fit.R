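# User-facing model fits and the panel_fit object.

finish_fit <- function(dat, opt, trait, control) {
  det <- opt$details
  s2 <- det$s2
  g <- opt$gamma
  comp <- list(sigma2 = s2, rho_r = opt$rho_r, rho_c = opt$rho_c)
  if (dat$b > 0L) comp$sigma2_u <- g$u * s2
  if (dat$kind == "baseline") comp$sigma2_t <- g$t * s2
  if (dat$kind == "genomic") {
    comp$sigma2_a <- g$a * s2
    comp$sigma2_p <- g$p * s2
  }
  if (dat$kind == "qtl") comp$sigma2_p <- g$p * s2

  # BLUPs through the MME solves: P y = (H0^-1 y - H0^-1 X beta) / s2
  iw <- det$iw
  RiW <- det$RiF[, iw, drop = FALSE]
  Riy <- det$RiF[, det$iy]
  RiX <- det$RiF[, det$ix, drop = FALSE]
  hy <- Riy - RiW %*% det$uy
  hX <- RiX - RiW %*% det$uX
  P0y <- as.vector(hy - hX %*% det$beta)
  Py <- P0y / s2
  v <- as.vector(crossprod(dat$Zg, Py))   # Z_g' P y in line order

  blup <- switch(dat$kind,
    baseline = tibble(line_id = dat$lines, g_t = comp$sigma2_t * v),
    genomic = tibble(line_id = dat$lines,
                     g_a = as.vector(comp$sigma2_a * (dat$Gsub %*% v)),
                     g_p = comp$sigma2_p * v),
    qtl = tibble(line_id = dat$lines, g_p = comp$sigma2_p * v))
  u_block <- if (dat$b > 0L) comp$sigma2_u * as.vector(crossprod(dat$Zb, Py))

  tau <- setNames(det$beta, colnames(dat$X))

  her <- switch(dat$kind,
    baseline = {
      H2 <- comp$sigma2_t / (comp$sigma2_t + s2)
      list(H2 = H2, h2 = NA_real_, additive_proportion = NA_real_)
    },
    genomic = {
      st <- comp$sigma2_a + comp$sigma2_p
      list(H2 = st / (st + s2), h2 = comp$sigma2_a / (st + s2),
           additive_proportion = 100 * comp$sigma2_a / st)
    },
    qtl = {
      list(H2 = comp$sigma2_p / (comp$sigma2_p + s2), h2 = NA_real_,
           additive_proportion = NA_real_)
    })

  structure(list(
    kind = dat$kind, trait = trait,
    components = comp, logL = opt$logL, tau = tau, blup = blup,
    u_block = u_block, heritability = her,
    convergence = list(code = opt$convergence, n_eval = opt$n_eval,
                       boundary = opt$boundary),
    n_plots = dat$n, n_lines = dat$m, p_fixed = dat$p,
    fingerprint = dat$fingerprint,
    solver = list(dat = dat, det = det, v = v, Py = Py)),
    class = "panel_fit")
}

fit_kind <- function(trial, trait, kind, grm = NULL, qtl_geno = NULL,
                     covariates = NULL, use_blocks = NULL, spatial = TRUE,
                     control = reml_control()) {
  dat <- build_reml_data(trial, trait, kind, grm = grm, qtl_geno = qtl_geno,
                         covariates = covariates, use_blocks = use_blocks,
                         spatial = spatial)
  opt <- reml_optimize(dat, control)
  finish_fit(dat, opt, trait, control)
}

#' Fit the baseline trial model
#'
#' REML fit of `y = X tau + Z u + Z_g g_t + e` with iid block effects `u`,
#' a total genetic effect per line `g_t ~ N(0, sigma2_t I)` and separable
#' AR1 x AR1 spatial plot error. Replicated plots (the repeated checks of a
#' non-replicated trial) are what separate `sigma2_t` from the spatial
#' error, so at least one line must be replicated.
#'
#' @param trial Trial tibble with `row`, `range`, `line_id`, an optional
#'   `block` column and the trait columns.
#' @param trait Trait column name.
#' @param covariates Optional trial columns entering X as standardized
#'   linear covariates (e.g. `c("row", "range")` for layout trends).
#' @param use_blocks Include the block term (default: when a `block`
#'   column exists).
#' @param spatial Estimate the AR1 parameters (`FALSE` fixes both at 0).
#' @param control A [reml_control()].
#' @return A `panel_fit` object; see [tidy.panel_fit()] and
#'   [glance.panel_fit()].
#' @export
fit_baseline <- function(trial, trait, covariates = NULL, use_blocks = NULL,
                         spatial = TRUE, control = reml_control()) {
  if (!anyDuplicated(trial$line_id[!is.na(trial[[trait]])])) {
    abort(paste("no replicated lines (checks): total genetic and error",
                "variance are confounded in the baseline model."),
          class = "fieldblup_input_error")
  }
  fit_kind(trial, trait, "baseline", covariates = covariates,
           use_blocks = use_blocks, spatial = spatial, control = control)
}

#' Fit the genomic (additive + residual genetic) trial model
#'
#' REML fit of `y = X tau + Z u + Z_g (g_a + g_p) + e` with additive
#' genetic values `g_a ~ N(0, sigma2_a G_s)` structured by the scaled
#' genomic relationship matrix and residual genetic values
#' `g_p ~ N(0, sigma2_p I)`. The log-likelihood is reported on the same
#' constant as [fit_baseline()], so fits on identical data are directly
#' comparable.
#'
#' @inheritParams fit_baseline
#' @param grm A [build_grm()] result covering all trial lines.
#' @return A `panel_fit` object carrying `g_a` and `g_p` BLUPs.
#' @export
fit_genomic <- function(trial, trait, grm, covariates = NULL,
                        use_blocks = NULL, spatial = TRUE,
                        control = reml_control()) {
  fit_kind(trial, trait, "genomic", grm = grm, covariates = covariates,
           use_blocks = use_blocks, spatial = spatial, control = control)
}

#' Fit the QTL fixed-effect trial model
#'
#' REML fit of `y = Z_g M_j beta_j + X tau + Z u + Z_g g_p + e`: the
#' selected markers enter as fixed covariates (their allele codes mapped
#' from lines to plots), and the total genetic effect is replaced by a
#' residual genetic effect `g_p ~ N(0, sigma2_p I)` since the markers
#' absorb the QTL-linked genetic variation. Line genetic values are
#' `M_j beta_j`.
#'
#' @inheritParams fit_baseline
#' @param selection A `qtl_selection` from [select_qtl()], or a character
#'   vector of marker names.
#' @param M Lines x markers genotype matrix holding the selected markers.
#' @return A `panel_fit`; `$qtl_effects` holds the estimated marker fixed
#'   effects and `$blup$g_qtl` the per-line QTL genetic values.
#' @export
fit_qtl <- function(trial, trait, selection, M, covariates = NULL,
                    use_blocks = NULL, spatial = TRUE,
                    control = reml_control()) {
  markers <- if (inherits(selection, "qtl_selection")) selection$marker else selection
  if (length(markers) && !all(markers %in% colnames(M))) {
    abort("selected markers missing from the genotype matrix.",
          class = "fieldblup_input_error")
  }
  qtl_geno <- M[, markers, drop = FALSE]
  fit <- fit_kind(trial, trait, "qtl", qtl_geno = qtl_geno,
                  covariates = covariates, use_blocks = use_blocks,
                  spatial = spatial, control = control)
  beta <- fit$tau[intersect(names(fit$tau), markers)]
  fit$qtl_effects <- tibble(marker = names(beta), beta = unname(beta))
  gq <- if (length(beta)) {
    as.vector(M[fit$blup$line_id, names(beta), drop = FALSE] %*% beta)
  } else {
    rep(0, nrow(fit$blup))
  }
  fit$blup$g_qtl <- gq
  fit
}

#' Heritability report for a fitted trial model
#'
#' Broad-sense heritability `H2 = sigma2_t / (sigma2_t + sigma2)` (with
#' `sigma2_t = sigma2_a + sigma2_p` for genomic fits), narrow-sense
#' `h2 = sigma2_a / (sigma2_t + sigma2)` and the additive proportion
#' `100 sigma2_a / (sigma2_a + sigma2_p)` (genomic fits only).
#'
#' @param fit A `panel_fit`.
#' @return One-row tibble: `kind`, `trait`, `H2`, `h2`,
#'   `additive_proportion`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "panel_fit"))
  h <- fit$heritability
  if (!is.na(h$H2) && h$H2 == 0) warn("zero total genetic variance; H2 = 0.")
  tibble(kind = fit$kind, trait = fit$trait, H2 = h$H2, h2 = h$h2,
         additive_proportion = h$additive_proportion)
}

#' Compare a baseline and a genomic fit of the same trait
#'
#' Reports the log-likelihood gain of partitioning the genetic variance
#' with the genomic relationship matrix. The percentage improvement is the
#' change in log-likelihood relative to the magnitude of the baseline
#' value, `100 (logL_g - logL_b) / |logL_b|`.
#'
#' @param baseline,genomic `panel_fit` objects fitted to identical data
#'   (enforced by fingerprint).
#' @return One-row tibble with logL values, `delta_logL`,
#'   `pct_improvement`, heritabilities and the additive proportion.
#' @export
compare_fits <- function(baseline, genomic) {
  stopifnot(inherits(baseline, "panel_fit"), inherits(genomic, "panel_fit"))
  if (baseline$kind != "baseline" || genomic$kind != "genomic") {
    abort("expected one baseline and one genomic fit.",
          class = "fieldblup_input_error")
  }
  if (!isTRUE(all.equal(baseline$fingerprint, genomic$fingerprint))) {
    abort("fits were not made on identical data (fingerprint mismatch).",
          class = "fieldblup_input_error")
  }
  tibble(trait = genomic$trait,
         logL_baseline = baseline$logL,
         logL_genomic = genomic$logL,
         delta_logL = genomic$logL - baseline$logL,
         pct_improvement = pct_improvement(baseline$logL, genomic$logL),
         H2_baseline = baseline$heritability$H2,
         H2_genomic = genomic$heritability$H2,
         h2_genomic = genomic$heritability$h2,
         additive_proportion = genomic$heritability$additive_proportion)
}

#' Percentage model-fit improvement from paired log-likelihoods
#'
#' `100 (logL_genomic - logL_baseline) / |logL_baseline|`, vectorised so a
#' published table of per-trait log-likelihood pairs can be summarised
#' directly.
#'
#' @param logL_baseline,logL_genomic Numeric vectors.
#' @return Numeric vector of percentage improvements.
#' @export
#' @examples
#' pct_improvement(-100, -50)
pct_improvement <- function(logL_baseline, logL_genomic) {
  100 * (logL_genomic - logL_baseline) / abs(logL_baseline)
}

#' @export
print.panel_fit <- function(x, ...) {
  cat(sprintf("%s model fit for trait `%s` (%d plots, %d lines)\n",
              x$kind, x$trait, x$n_plots, x$n_lines))
  cat(sprintf("  REML logL = %.3f (%d evaluations)\n", x$logL,
              x$convergence$n_eval))
  comp <- x$components
  cat("  components:",
      paste(sprintf("%s = %.4g", names(comp), unlist(comp)), collapse = ", "),
      "\n")
  if (length(x$convergence$boundary)) {
    cat("  boundary components:",
        paste(x$convergence$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy the variance components of a `panel_fit`
#'
#' @param x A `panel_fit`.
#' @param ... Unused.
#' @return Tibble: `component`, `estimate`, `boundary`.
#' @method tidy panel_fit
#' @export
tidy.panel_fit <- function(x, ...) {
  comp <- x$components
  tibble(component = names(comp),
         estimate = unlist(comp, use.names = FALSE),
         boundary = sub("^sigma2_", "", names(comp)) %in%
           x$convergence$boundary)
}

#' One-row summary of a `panel_fit`
#'
#' @param x A `panel_fit`.
#' @param ... Unused.
#' @return Tibble: `kind`, `trait`, `logL`, `H2`, `h2`,
#'   `additive_proportion`, `n_plots`, `n_lines`, `converged`.
#' @method glance panel_fit
#' @export
glance.panel_fit <- function(x, ...) {
  tibble(kind = x$kind, trait = x$trait, logL = x$logL,
         H2 = x$heritability$H2, h2 = x$heritability$h2,
         additive_proportion = x$heritability$additive_proportion,
         n_plots = x$n_plots, n_lines = x$n_lines,
         converged = x$convergence$code == 0L)
}

#' Variance component plot for a fitted model
#'
#' @param object A `panel_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_fit
#' @export
autoplot.panel_fit <- function(object, ...) {
  td <- tidy(object) %>% filter(!.data$component %in% c("rho_r", "rho_c"))
  ggplot(td, aes(x = .data$component, y = .data$estimate)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "variance estimate",
         title = sprintf("%s fit: %s", object$kind, object$trait)) +
    theme_minimal()
}
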