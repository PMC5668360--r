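# Synthetic panel generator: maps, meiosis, traits, trials, masking.

test_that("simulated maps place markers on sorted unique grids", {
  cfg <- sim_config(n_lines = 10, n_chromosomes = 1, markers_per_chrom = 2,
                    chrom_length = 100, trial_ranges = 4, seed = 1)
  expect_equal(sim_map(cfg)$pos, c(0, 100))

  cfg21 <- sim_config(n_lines = 10, n_chromosomes = 21,
                      markers_per_chrom = 100, trial_ranges = 4, seed = 1)
  map <- sim_map(cfg21)
  expect_equal(nrow(map), 2100)
  expect_equal(length(unique(map$chrom)), 21)
  expect_true(all(tapply(map$pos, map$chrom, function(p) all(diff(p) >= 0))))
  expect_false(anyDuplicated(map$marker) > 0)

  cfgj <- sim_config(n_lines = 10, n_chromosomes = 2, markers_per_chrom = 30,
                     trial_ranges = 4, placement = "jitter", seed = 5)
  expect_identical(sim_map(cfgj), sim_map(cfgj))
})

test_that("meiosis follows the Haldane model", {
  pos <- c(0, 50)
  h1 <- c(1, 1); h2 <- c(-1, -1)
  set.seed(42)
  gam <- replicate(2000, fieldblup:::meiosis_gamete(h1, h2, pos, 50))
  rec <- mean(gam[1, ] != gam[2, ])
  c_hald <- (1 - exp(-2 * 50 / 100)) / 2
  se <- sqrt(c_hald * (1 - c_hald) / 2000)
  expect_lt(abs(rec - c_hald), 3 * se)

  # zero distance: no recombinant gametes ever
  gam0 <- replicate(200, fieldblup:::meiosis_gamete(h1, h2, c(25, 25), 50))
  expect_true(all(gam0[1, ] == gam0[2, ]))
})

test_that("tightly linked markers are in complete LD in a biparental cross", {
  # with two founders, allele state is determined by haplotype origin, so
  # coincident loci are perfectly correlated in any derived population
  for (seed in 1:10) {
    cfg <- sim_config(n_lines = 150, n_founders = 2, n_chromosomes = 1,
                      markers_per_chrom = 2, chrom_length = 1e-6,
                      trial_ranges = 12, seed = seed)
    M <- sim_genotypes(sim_map(cfg), cfg)
    if (sd(M[, 1]) > 0 && sd(M[, 2]) > 0) break  # need both polymorphic
  }
  expect_equal(abs(cor(M[, 1], M[, 2])), 1, tolerance = 1e-12)
})

test_that("selfing drives heterozygosity down geometrically", {
  cfg <- sim_config(n_lines = 120, n_founders = 10, n_chromosomes = 2,
                    markers_per_chrom = 50, selfing_generations = 6,
                    trial_ranges = 11, seed = 3)
  M <- sim_genotypes(sim_map(cfg), cfg)
  expect_lte(mean(M == 0), 3 * 2^-6)
  expect_true(all(M %in% c(-1, 0, 1)))
})

test_that("trait truth respects the g_a = M effects identity and scaling", {
  pan <- small_panel()
  expect_equal(pan$geno %*% pan$truth$marker_effects, pan$truth$g_a,
               tolerance = 1e-12)
  expect_equal(var(as.vector(pan$truth$g_a)), 0.8, tolerance = 1e-6)

  # zero polygenic variance -> identically zero additive values
  t0 <- sim_traits(pan$geno, trait_spec("z", polygenic_var = 0,
                                        residual_genetic_var = 0), seed = 1)
  expect_true(all(t0$g_a == 0))

  # a single dominant-effect QTL determines the additive ranking
  t1 <- sim_traits(pan$geno, trait_spec("q", n_qtl = 1, qtl_effect_sd = 50,
                                        polygenic_var = 1e-8), seed = 4)
  qcol <- pan$geno[, t1$qtl$q]
  expect_equal(abs(cor(t1$g_a[, 1], qcol)), 1, tolerance = 1e-4)
})

test_that("cross-trait additive correlations are recovered at scale", {
  cfg <- sim_config(n_lines = 2000, n_founders = 40, n_chromosomes = 2,
                    markers_per_chrom = 50, selfing_generations = 4,
                    trial_ranges = 46, seed = 9,
                    trait_specs = list(trait_spec("a"), trait_spec("b")))
  M <- sim_genotypes(sim_map(cfg), cfg)
  tr <- sim_traits(M, cfg$trait_specs,
                   additive_cor = matrix(c(1, 0.5, 0.5, 1), 2), seed = 10)
  expect_lt(abs(cor(tr$g_a[, 1], tr$g_a[, 2]) - 0.5), 0.05)
})

test_that("non-PSD cross-trait correlation is rejected", {
  pan <- small_panel()
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(
    sim_traits(pan$geno, list(trait_spec("a"), trait_spec("b")),
               additive_cor = bad),
    class = "fieldblup_config_error")
})

test_that("trial layout honours checks, blocks and grid size", {
  pan <- small_panel()
  trial <- pan$trial
  ci <- pan$config$check_interval
  # the designated check occupies every check_interval-th plot in plot order
  expect_true(all(trial$is_check[seq(1, nrow(trial), by = ci)]))
  expect_equal(length(unique(trial$line_id)), pan$config$n_lines)
  # unreplicated test lines
  reps <- table(trial$line_id)
  expect_true(all(reps[names(reps) != trial$line_id[1]] == 1))
  expect_false(anyDuplicated(trial[c("row", "range")]) > 0)

  expect_error(
    sim_trial(pan$truth, sim_config(n_lines = 80, trial_rows = 5,
                                    trial_ranges = 5, seed = 1)),
    class = "fieldblup_config_error")
})

test_that("spatial error field matches its AR1 x AR1 law", {
  lag1 <- function(E, along = c("row", "col")) {
    along <- match.arg(along)
    if (along == "row") cor(as.vector(E[-1, ]), as.vector(E[-nrow(E), ]))
    else cor(as.vector(E[, -1]), as.vector(E[, -ncol(E)]))
  }
  base <- list(n_lines = 2000, n_founders = 4, n_chromosomes = 1,
               markers_per_chrom = 2, trial_rows = 100, trial_ranges = 24,
               check_interval = 11L)
  reshape_field <- function(trial) {
    e <- attr(trial, "truth_trial")$spatial_error[, 1]
    E <- matrix(NA_real_, max(trial$row), max(trial$range))
    E[cbind(trial$row, trial$range)] <- e
    E
  }
  cfg0 <- do.call(sim_config, c(base, list(
    trait_specs = list(trait_spec("y", polygenic_var = 0,
                                  residual_genetic_var = 0, error_var = 1,
                                  block_var = 0, rho_row = 0, rho_col = 0)),
    seed = 21)))
  M <- matrix(rep(c(-1, 1), 2000), 2000, 2,
              dimnames = list(sprintf("L%05d", 1:2000), c("m1", "m2")))
  tr0 <- sim_traits(M, cfg0$trait_specs, seed = 21)
  E0 <- reshape_field(sim_trial(tr0, cfg0))
  expect_lt(abs(lag1(E0, "row")), 0.05)
  expect_lt(abs(lag1(E0, "col")), 0.05)

  cfg6 <- do.call(sim_config, c(base, list(
    trait_specs = list(trait_spec("y", polygenic_var = 0,
                                  residual_genetic_var = 0, error_var = 1,
                                  block_var = 0, rho_row = 0.6,
                                  rho_col = 0)),
    seed = 22)))
  tr6 <- sim_traits(M, cfg6$trait_specs, seed = 22)
  E6 <- reshape_field(sim_trial(tr6, cfg6))
  expect_lt(abs(lag1(E6, "row") - 0.6), 0.07)

  # degenerate: all variances zero -> every plot equals the intercept
  cfgd <- do.call(sim_config, c(base, list(
    trait_specs = list(trait_spec("y", polygenic_var = 0,
                                  residual_genetic_var = 0, error_var = 0,
                                  block_var = 0, mean = 3.5)),
    seed = 23)))
  trd <- sim_traits(M, cfgd$trait_specs, seed = 23)
  expect_true(all(sim_trial(trd, cfgd)$y == 3.5))
})

test_that("masking is uniform, recorded and seed-stable", {
  pan <- small_panel()
  expect_identical(mask_genotypes(pan$geno, 0), {
    M <- pan$geno; attr(M, "mask") <- attr(mask_genotypes(pan$geno, 0), "mask"); M
  })
  m1 <- mask_genotypes(pan$geno, 0.05, seed = 11)
  m2 <- mask_genotypes(pan$geno, 0.05, seed = 11)
  expect_identical(m1, m2)
  n_na <- sum(is.na(m1))
  expected <- length(pan$geno) * 0.05
  expect_lt(abs(n_na - expected), 3 * sqrt(expected * 0.95))
  expect_error(mask_genotypes(pan$geno, 1),
               class = "fieldblup_config_error")
})
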