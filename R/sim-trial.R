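#' Simulate a non-replicated field trial with repeated checks
#'
#' Lays a `trial_rows x trial_ranges` grid out in plot order (range-major:
#' all rows of range 1, then range 2, ...). Every `check_interval`-th plot in
#' that order carries the designated check line (the panel's first line);
#' the remaining plots each carry one unreplicated test line in random
#' order, and any surplus plots receive extra check replicates. Phenotypes
#' are built as intercept + block effect + `g_a` + `g_p` + spatial error,
#' with the error field drawn exactly from the separable AR1 x AR1
#' covariance via its Kronecker-structured Cholesky factor.
#'
#' @param truth A `panel_truth` from [sim_traits()].
#' @param config A [sim_config()].
#' @return Trial tibble (`plot`, `row`, `range`, `block`, `line_id`,
#'   `is_check`, one column per trait) with attribute `truth_trial`
#'   containing the realised block effects and spatial fields per trait.
#' @export
sim_trial <- function(truth, config) {
  stopifnot(inherits(truth, "panel_truth"), inherits(config, "sim_config"))
  nr <- config$trial_rows
  nc <- config$trial_ranges
  ci <- config$check_interval
  n_plots <- nr * nc
  lines <- rownames(truth$g_a)
  n <- length(lines)
  n_checks <- ceiling(n_plots / ci)
  if (n_plots - n_checks < n - 1L) {
    abort("trial layout too small for the panel.",
          class = "fieldblup_config_error")
  }

  with_seed(config$seed + 3L, {
    plot <- seq_len(n_plots)
    range <- rep(seq_len(nc), each = nr)
    row <- rep(seq_len(nr), times = nc)
    block <- (plot - 1L) %/% config$block_size + 1L
    is_check <- ((plot - 1L) %% ci) == 0L
    check_line <- lines[1L]
    line_id <- rep(check_line, n_plots)
    open <- which(!is_check)
    test_plots <- sample(open, n - 1L)
    line_id[test_plots] <- lines[-1L]
    is_check <- line_id == check_line

    trial <- tibble(plot = plot, row = row, range = range, block = block,
                    line_id = line_id, is_check = is_check)

    nb <- max(block)
    specs <- truth$trait_specs
    u_all <- matrix(0, nb, length(specs))
    e_all <- matrix(0, n_plots, length(specs))
    for (t in seq_along(specs)) {
      spec <- specs[[t]]
      u <- if (spec$block_var > 0) rnorm(nb, sd = sqrt(spec$block_var)) else numeric(nb)
      Lr <- t(chol(ar1_mat(nr, spec$rho_row)))
      Lc <- t(chol(ar1_mat(nc, spec$rho_col)))
      E <- Lr %*% matrix(rnorm(nr * nc), nr, nc) %*% t(Lc)
      e <- sqrt(spec$error_var) * E[cbind(row, range)]
      idx <- match(line_id, lines)
      y <- spec$mean + u[block] + truth$g_a[idx, t] + truth$g_p[idx, t] + e
      trial[[spec$name]] <- as.vector(y)
      u_all[, t] <- u
      e_all[, t] <- as.vector(e)
    }
    colnames(u_all) <- colnames(e_all) <- vapply(specs, `[[`, "", "name")
    attr(trial, "truth_trial") <- list(block_effects = u_all,
                                       spatial_error = e_all)
    trial
  })
}

#' Simulate a complete synthetic breeding panel
#'
#' Convenience wrapper running [sim_map()], [sim_genotypes()],
#' [sim_traits()] and [sim_trial()] under one configuration and seed.
#'
#' @param config A [sim_config()].
#' @param additive_cor Optional cross-trait additive correlation matrix
#'   passed to [sim_traits()].
#' @return List with elements `map`, `geno`, `truth`, `trial`, `config`.
#' @export
#' @examples
#' pan <- sim_panel(sim_config(n_lines = 60, n_chromosomes = 2,
#'                             markers_per_chrom = 40, trial_ranges = 6,
#'                             seed = 42))
#' dim(pan$geno)
sim_panel <- function(config, additive_cor = NULL) {
  map <- sim_map(config)
  geno <- sim_genotypes(map, config)
  truth <- sim_traits(geno, config$trait_specs, additive_cor = additive_cor,
                      seed = config$seed + 2L)
  trial <- sim_trial(truth, config)
  list(map = map, geno = geno, truth = truth, trial = trial, config = config)
}
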