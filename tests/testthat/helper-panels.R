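# Shared synthetic fixtures, built once per test run and cached.

panel_cache <- new.env(parent = emptyenv())

# A small polygenic panel with blocks and spatial error; used across the
# model-fitting and prediction tests.
small_panel <- function() {
  if (is.null(panel_cache$small)) {
    cfg <- sim_config(n_lines = 80, n_founders = 12, n_chromosomes = 3,
                      markers_per_chrom = 40, chrom_length = 120,
                      selfing_generations = 6, trial_ranges = 8,
                      trait_specs = list(trait_spec(
                        "y", polygenic_var = 0.8, residual_genetic_var = 0.2,
                        error_var = 0.4, block_var = 0.1,
                        rho_row = 0.35, rho_col = 0.35)),
                      seed = 7)
    pan <- sim_panel(cfg)
    pan$grm <- build_grm(pan$geno)
    panel_cache$small <- pan
  }
  panel_cache$small
}

small_fit_genomic <- function() {
  if (is.null(panel_cache$small_fg)) {
    pan <- small_panel()
    panel_cache$small_fg <- fit_genomic(pan$trial, "y", pan$grm)
  }
  panel_cache$small_fg
}

small_fit_baseline <- function() {
  if (is.null(panel_cache$small_fb)) {
    pan <- small_panel()
    panel_cache$small_fb <- fit_baseline(pan$trial, "y")
  }
  panel_cache$small_fb
}

# A strong-LD panel (few founders, dense map) for LD-driven operations:
# chromosome assignment, KNN imputation, LD decay.
ld_panel <- function() {
  if (is.null(panel_cache$ld)) {
    cfg <- sim_config(n_lines = 250, n_founders = 4, n_chromosomes = 2,
                      markers_per_chrom = 60, chrom_length = 150,
                      selfing_generations = 4, trial_ranges = 15, seed = 31)
    map <- sim_map(cfg)
    panel_cache$ld <- list(map = map, geno = sim_genotypes(map, cfg),
                           config = cfg)
  }
  panel_cache$ld
}

# A tiny trial on a complete grid for dense-oracle comparisons.
tiny_panel <- function(seed = 3, n_lines = 16, nr = 5, nc = 4) {
  cfg <- sim_config(n_lines = n_lines, n_founders = 6, n_chromosomes = 2,
                    markers_per_chrom = 15, trial_rows = nr,
                    trial_ranges = nc, check_interval = 5L,
                    block_size = nr,
                    trait_specs = list(trait_spec(
                      "y", polygenic_var = 1, residual_genetic_var = 0.3,
                      error_var = 0.5, block_var = 0.2,
                      rho_row = 0.3, rho_col = 0.2)),
                    seed = seed)
  pan <- sim_panel(cfg)
  pan$grm <- build_grm(pan$geno)
  pan
}

# Dense brute-force REML log-likelihood: builds H explicitly from the
# variance components and evaluates the restricted likelihood with base
# linear algebra only. Independent of the package's structured solver.
dense_reml_loglik <- function(trial, trait, comp, Gs = NULL,
                              kind = "genomic", qtl_geno = NULL) {
  trial <- trial[!is.na(trial[[trait]]), ]
  trial <- trial[order(trial$row, trial$range), ]
  y <- trial[[trait]]
  n <- length(y)
  lines <- sort(unique(trial$line_id))
  Zg <- outer(trial$line_id, lines, "==") * 1
  X <- matrix(1, n, 1)
  if (!is.null(qtl_geno) && ncol(qtl_geno) > 0) {
    X <- cbind(X, qtl_geno[match(trial$line_id, rownames(qtl_geno)), ,
                           drop = FALSE])
  }
  R <- comp$rho_r^abs(outer(trial$row, trial$row, "-")) *
    comp$rho_c^abs(outer(trial$range, trial$range, "-"))
  H <- comp$sigma2 * R
  if (!is.null(comp$sigma2_u)) {
    Zb <- outer(trial$block, sort(unique(trial$block)), "==") * 1
    H <- H + comp$sigma2_u * tcrossprod(Zb)
  }
  K <- switch(kind,
    baseline = comp$sigma2_t * diag(length(lines)),
    genomic = comp$sigma2_a * Gs[lines, lines] +
      comp$sigma2_p * diag(length(lines)),
    qtl = comp$sigma2_p * diag(length(lines)))
  H <- H + Zg %*% K %*% t(Zg)
  Hi <- solve(H)
  XHX <- t(X) %*% Hi %*% X
  P <- Hi - Hi %*% X %*% solve(XHX, t(X) %*% Hi)
  as.numeric(-0.5 * (determinant(H)$modulus + determinant(XHX)$modulus +
                       t(y) %*% P %*% y + (n - ncol(X)) * log(2 * pi)))
}

# Dense P matrix for BLUP oracles.
dense_P <- function(trial, trait, comp, Gs, kind = "genomic") {
  trial <- trial[!is.na(trial[[trait]]), ]
  trial <- trial[order(trial$row, trial$range), ]
  n <- nrow(trial)
  lines <- sort(unique(trial$line_id))
  Zg <- outer(trial$line_id, lines, "==") * 1
  X <- matrix(1, n, 1)
  R <- comp$rho_r^abs(outer(trial$row, trial$row, "-")) *
    comp$rho_c^abs(outer(trial$range, trial$range, "-"))
  H <- comp$sigma2 * R
  if (!is.null(comp$sigma2_u)) {
    Zb <- outer(trial$block, sort(unique(trial$block)), "==") * 1
    H <- H + comp$sigma2_u * tcrossprod(Zb)
  }
  K <- switch(kind,
    baseline = comp$sigma2_t * diag(length(lines)),
    genomic = comp$sigma2_a * Gs[lines, lines] +
      comp$sigma2_p * diag(length(lines)))
  H <- H + Zg %*% K %*% t(Zg)
  Hi <- solve(H)
  XHX <- t(X) %*% Hi %*% X
  list(P = Hi - Hi %*% X %*% solve(XHX, t(X) %*% Hi),
       Zg = Zg, y = trial[[trait]], lines = lines)
}
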