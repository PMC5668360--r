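#' Trait architecture specification for the synthetic panel generator
#'
#' Describes one trait's genetic architecture and trial-level variance
#' structure. Variances are on the trait scale (units squared); the default
#' partition (additive 0.8, residual genetic 0.2, plot error 0.43) gives a
#' broad-sense heritability of about 0.7 with 80% of the genetic variance
#' additive, typical of the moderately heritable traits scored in large
#' inbred cereal panels.
#'
#' @param name Trait name used as the phenotype column in the trial table.
#' @param n_qtl Number of major QTL (0 = purely polygenic trait).
#' @param qtl_effect_sd Standard deviation of the extra allele-substitution
#'   effects given to the `n_qtl` major loci (trait units).
#' @param polygenic_var Target variance of the additive genetic values
#'   `g_a = M effects` across lines.
#' @param residual_genetic_var Variance of the residual (non-additive)
#'   genetic values `g_p`.
#' @param error_var Variance of the spatial plot error field.
#' @param block_var Variance of iid block effects.
#' @param rho_row,rho_col AR1 autocorrelation of the plot error along trial
#'   rows and ranges (each in (-1, 1)).
#' @param mean Trait intercept.
#' @return A `trait_spec` list.
#' @export
#' @examples
#' trait_spec("yield", polygenic_var = 0.7, residual_genetic_var = 0.3)
trait_spec <- function(name = "trait",
                       n_qtl = 0L,
                       qtl_effect_sd = 0,
                       polygenic_var = 0.8,
                       residual_genetic_var = 0.2,
                       error_var = 0.43,
                       block_var = 0.1,
                       rho_row = 0.4,
                       rho_col = 0.4,
                       mean = 0) {
  n_qtl <- check_count(n_qtl, "n_qtl", min = 0L)
  for (v in c("qtl_effect_sd", "polygenic_var", "residual_genetic_var",
              "error_var", "block_var")) {
    val <- get(v)
    if (length(val) != 1L || !is.finite(val) || val < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", v),
            class = "fieldblup_config_error")
    }
  }
  check_fraction(rho_row, "rho_row", lo = -0.999, hi = 0.999)
  check_fraction(rho_col, "rho_col", lo = -0.999, hi = 0.999)
  structure(list(name = name, n_qtl = n_qtl, qtl_effect_sd = qtl_effect_sd,
                 polygenic_var = polygenic_var,
                 residual_genetic_var = residual_genetic_var,
                 error_var = error_var, block_var = block_var,
                 rho_row = rho_row, rho_col = rho_col, mean = mean),
            class = "trait_spec")
}

#' Configuration for the synthetic breeding-panel generator
#'
#' The defaults emulate the study conditions of a large single-site wheat
#' breeding panel: a 10,375-line panel genotyped at roughly 17,000 SNPs on 21
#' chromosomes, phenotyped in a non-replicated 476 x 24 field trial with one
#' repeated check per 11 plots. Tests and examples use much smaller
#' configurations; every dimension scales freely.
#'
#' @param n_lines Number of test lines in the panel (the designated check
#'   line is one of them).
#' @param n_founders Number of founder inbreds crossed to create the panel.
#' @param n_chromosomes,chrom_length,markers_per_chrom Genetic map layout;
#'   `chrom_length` in cM.
#' @param selfing_generations Rounds of selfing after the founder cross;
#'   residual heterozygosity halves each round.
#' @param trait_specs List of [trait_spec()] objects.
#' @param trial_rows,trial_ranges Field trial grid dimensions. `NULL` (the
#'   default for `trial_rows`) derives the smallest row count that fits all
#'   lines plus checks at the given number of ranges.
#' @param check_interval One check plot every `check_interval` plots in plot
#'   order.
#' @param block_size Plots per block (contiguous in plot order). `NULL` uses
#'   one block per range.
#' @param allele_coding `"pm1"` codes homozygotes -1/+1 with residual
#'   heterozygotes 0; `"01"` codes 0/1 with heterozygotes 0.5.
#' @param placement Marker placement along chromosomes: evenly spaced or an
#'   evenly spaced grid with random jitter.
#' @param seed Integer seed driving all simulation randomness.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 200, n_chromosomes = 3, markers_per_chrom = 50,
#'                   seed = 1)
sim_config <- function(n_lines = 10375L,
                       n_founders = 50L,
                       n_chromosomes = 21L,
                       chrom_length = 150,
                       markers_per_chrom = 820L,
                       selfing_generations = 6L,
                       trait_specs = list(trait_spec()),
                       trial_rows = NULL,
                       trial_ranges = 24L,
                       check_interval = 11L,
                       block_size = NULL,
                       allele_coding = c("pm1", "01"),
                       placement = c("uniform", "jitter"),
                       seed = 1L) {
  n_lines <- check_count(n_lines, "n_lines", 2L)
  n_founders <- check_count(n_founders, "n_founders", 2L)
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  markers_per_chrom <- check_count(markers_per_chrom, "markers_per_chrom", 2L)
  selfing_generations <- check_count(selfing_generations, "selfing_generations", 0L)
  check_interval <- check_count(check_interval, "check_interval", 2L)
  trial_ranges <- check_count(trial_ranges, "trial_ranges")
  if (length(chrom_length) != 1L || !is.finite(chrom_length) || chrom_length <= 0) {
    abort("`chrom_length` must be a positive length in cM.",
          class = "fieldblup_config_error")
  }
  if (inherits(trait_specs, "trait_spec")) trait_specs <- list(trait_specs)
  if (!length(trait_specs) || !all(vapply(trait_specs, inherits, TRUE, "trait_spec"))) {
    abort("`trait_specs` must be a list of trait_spec() objects.",
          class = "fieldblup_config_error")
  }
  nm <- vapply(trait_specs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    abort("trait names must be unique.", class = "fieldblup_config_error")
  }
  if (is.null(trial_rows)) {
    # smallest grid with enough non-check plots for all test lines
    ci <- check_interval
    trial_rows <- ceiling(n_lines / (trial_ranges * (ci - 1) / ci))
    while (trial_rows * trial_ranges -
           ceiling(trial_rows * trial_ranges / ci) < n_lines - 1L) {
      trial_rows <- trial_rows + 1L
    }
  }
  trial_rows <- check_count(trial_rows, "trial_rows")
  n_plots <- trial_rows * trial_ranges
  n_checks <- ceiling(n_plots / check_interval)
  if (n_plots - n_checks < n_lines - 1L) {
    abort(sprintf(
      "trial layout too small: %d plots minus %d checks < %d test lines.",
      n_plots, n_checks, n_lines - 1L), class = "fieldblup_config_error")
  }
  if (is.null(block_size)) block_size <- trial_rows
  block_size <- check_count(block_size, "block_size")
  structure(list(
    n_lines = n_lines, n_founders = n_founders,
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    markers_per_chrom = markers_per_chrom,
    selfing_generations = selfing_generations,
    trait_specs = trait_specs,
    trial_rows = trial_rows, trial_ranges = trial_ranges,
    check_interval = check_interval, block_size = block_size,
    allele_coding = match.arg(allele_coding),
    placement = match.arg(placement),
    seed = as.integer(seed)), class = "sim_config")
}
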