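#' Run the full analysis pipeline
#'
#' Binds the stages end to end: obtain data (simulate a synthetic panel,
#' or read genotype/map/trial files), MAF-filter, LD-assign unmapped
#' markers and impute, build the scaled GRM, fit baseline and genomic
#' models per trait, back-solve marker effects, scan and select QTL,
#' cross-validate the prediction methods, correlate traits, and summarise
#' the map and LD decay. Every stage's parameters and seed come from the
#' config, so a rerun with the same config reproduces identical output.
#'
#' @param config A list:
#' \describe{
#'   \item{sim}{A [sim_config()] to simulate a panel, or `NULL` when
#'     `paths` is given.}
#'   \item{paths}{List with `genotypes`, `map`, `trial` file paths
#'     (ignored when `sim` is given).}
#'   \item{traits}{Trait columns to analyse; default all trait columns.}
#'   \item{missing_rate}{Optional masking applied to simulated genotypes
#'     before imputation (exercises the QC stages; default 0.01 when
#'     simulating).}
#'   \item{maf_threshold, knn_k, qtl_window, cv_folds, cv_methods,
#'     ld_max_sep, spatial}{Stage parameters with the pipeline defaults
#'     0.01, 10, 25, 5, all methods, 30 cM, TRUE.}
#'   \item{seed}{Integer seed (default 1).}
#' }
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as CSV/TSV files.
#' @return A list of stage results: `trial`, `geno`, `map`, `grm` and
#'   tibbles `fits` (per-trait model comparison), `marker_effects`,
#'   `qtl`, `cv`, `correlations`, `correlation_summary`, `map_summary`,
#'   `ld_bins`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- utils::modifyList(
    list(sim = NULL, paths = NULL, traits = NULL, missing_rate = NULL,
         maf_threshold = 0.01, knn_k = 10L, qtl_window = 25,
         cv_folds = 5L, cv_methods = c("genomic", "qtl1", "qtl5"),
         ld_max_sep = 30, spatial = TRUE, seed = 1L),
    config)
  stage <- function(name) inform(sprintf("[pipeline] %s", name))

  if (!is.null(cfg$sim)) {
    stage("simulate synthetic panel")
    pan <- sim_panel(cfg$sim)
    map <- pan$map; geno <- pan$geno; trial <- pan$trial
    if (is.null(cfg$missing_rate)) cfg$missing_rate <- 0.01
    if (cfg$missing_rate > 0) {
      geno <- mask_genotypes(geno, cfg$missing_rate, seed = cfg$seed + 11L)
    }
  } else {
    if (is.null(cfg$paths)) {
      abort("config needs either `sim` or `paths`.",
            class = "fieldblup_config_error")
    }
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) {
        abort(sprintf("input file does not exist: %s", p),
              class = "fieldblup_config_error")
      }
    }
    stage("read inputs")
    geno <- read_genotypes(cfg$paths$genotypes)
    map <- read_map(cfg$paths$map)
    trial <- read_trial(cfg$paths$trial)
    pan <- NULL
  }

  stage("MAF filter")
  geno <- maf_filter(geno, cfg$maf_threshold)
  map <- map %>% filter(.data$marker %in% colnames(geno))

  if (anyNA(geno)) {
    stage("KNN imputation (per chromosome, LD-assigned unmapped markers)")
    geno <- knn_impute(geno, map, k = cfg$knn_k)
  }

  stage("genomic relationship matrix")
  grm <- build_grm(geno)

  traits <- cfg$traits %||% setdiff(
    names(trial)[vapply(trial, is.numeric, TRUE)],
    c("plot", "row", "range", "block"))

  fits <- list(); effects <- list(); qtl <- list(); cvs <- list()
  gen_fits <- list()
  for (tr in traits) {
    stage(sprintf("fit models: %s", tr))
    fb <- fit_baseline(trial, tr, spatial = cfg$spatial)
    fg <- fit_genomic(trial, tr, grm, spatial = cfg$spatial)
    gen_fits[[tr]] <- fg
    fits[[tr]] <- compare_fits(fb, fg)
    stage(sprintf("marker effects + QTL scan: %s", tr))
    eff <- backsolve_marker_effects(fg, geno, grm)
    effects[[tr]] <- eff %>% mutate(trait = tr)
    qtl[[tr]] <- select_qtl(eff, map, n_select = 5L,
                            window = cfg$qtl_window) %>%
      mutate(trait = tr)
    stage(sprintf("cross-validation: %s", tr))
    cvs[[tr]] <- tidy(cross_validate(
      trial, tr, geno, map, grm = grm, methods = cfg$cv_methods,
      k = cfg$cv_folds, seed = cfg$seed, window = cfg$qtl_window,
      spatial = cfg$spatial))
  }

  stage("trait correlations")
  gc <- if (length(traits) >= 2L) genetic_correlations(gen_fits)
  stage("map summary + LD decay")
  msum <- summarize_map(map)
  ld <- ld_r2(geno, map, max_separation = cfg$ld_max_sep)
  ld_bins <- ld_decay_bins(ld, ld_default_bins(max(cfg$ld_max_sep, 20)))

  out <- list(trial = trial, geno = geno, map = map, grm = grm,
              fits = bind_rows(fits),
              marker_effects = bind_rows(effects),
              qtl = bind_rows(qtl), cv = bind_rows(cvs),
              correlations = gc,
              correlation_summary = if (length(traits) >= 3L)
                correlation_summary(gc),
              map_summary = msum, ld_bins = ld_bins,
              config = cfg, truth = if (!is.null(pan)) pan$truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(geno, file.path(out_dir, "genotypes.tsv"))
    write_map(map, file.path(out_dir, "map.csv"))
    write_trial(trial, file.path(out_dir, "trial.csv"))
    readr::write_csv(out$fits, file.path(out_dir, "model_fits.csv"))
    readr::write_csv(out$qtl, file.path(out_dir, "qtl_selection.csv"))
    readr::write_csv(out$cv, file.path(out_dir, "cv_accuracy.csv"))
    readr::write_csv(out$map_summary, file.path(out_dir, "map_summary.csv"))
    readr::write_csv(out$ld_bins, file.path(out_dir, "ld_bins.csv"))
  }
  out
}
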