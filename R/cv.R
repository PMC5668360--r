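# Fivefold cross-validation of genomic and QTL-based prediction.

#' Cross-validate genomic and QTL prediction for one trait
#'
#' Randomly partitions the panel lines into `k` near-equal folds. For each
#' fold the validation lines' plots are removed, the genomic model is
#' refitted on the training plots, marker effects are back-solved and the
#' validation lines predicted as `M g_m`; QTL methods re-select markers
#' within the training fold by default (no information leakage; set
#' `qtl_selection = "full"` to fix the selection from the full-data scan
#' as an upper bound), re-estimate their fixed effects on the training
#' fold and predict as `M_j beta_j`. Pooled validation predictions are
#' scored two ways: `accuracy_additive` correlates them with the full-data
#' genomic model's additive genetic values, and `accuracy_total`
#' correlates them with the full-data baseline model's total genetic
#' values divided by the square root of the baseline heritability.
#'
#' @param trial Trial tibble.
#' @param trait Trait column name.
#' @param M Complete lines x markers genotype matrix.
#' @param map Map tibble (QTL methods; may be `NULL` for genomic-only).
#' @param grm Optional pre-built [build_grm()]; built from `M` if absent.
#' @param methods Subset of `"genomic"`, `"qtl1"`, `"qtl5"`.
#' @param k Number of folds (default fivefold).
#' @param seed Integer seed for the fold permutation.
#' @param qtl_selection `"fold"` (reselect per training fold) or
#'   `"full"` (selection fixed from the full-data fit).
#' @param window QTL exclusion window in cM.
#' @param spatial,use_blocks,control Passed to the fitting functions.
#' @return A `panel_cv` object: `$accuracy` (per method), `$predictions`
#'   (per line), `$folds`, `$reference` (full-fit summaries), `$seed`.
#' @export
cross_validate <- function(trial, trait, M, map = NULL, grm = NULL,
                           methods = c("genomic", "qtl1", "qtl5"),
                           k = 5L, seed = 1L,
                           qtl_selection = c("fold", "full"),
                           window = 25, spatial = TRUE, use_blocks = NULL,
                           control = reml_control()) {
  qtl_selection <- match.arg(qtl_selection)
  k <- check_count(k, "k", min = 2L)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(grm)) grm <- build_grm(M)
  lines <- sort(unique(trial$line_id))
  if (!all(lines %in% rownames(M))) {
    abort("genotypes missing for some trial lines.",
          class = "fieldblup_input_error")
  }

  full_gen <- fit_genomic(trial, trait, grm, spatial = spatial,
                          use_blocks = use_blocks, control = control)
  full_base <- fit_baseline(trial, trait, spatial = spatial,
                            use_blocks = use_blocks, control = control)
  g_a_full <- setNames(full_gen$blup$g_a, full_gen$blup$line_id)
  g_t_full <- setNames(full_base$blup$g_t, full_base$blup$line_id)
  H2_base <- full_base$heritability$H2

  full_sel <- list()
  if (qtl_selection == "full" && any(grepl("^qtl", methods))) {
    eff_full <- backsolve_marker_effects(full_gen, M, grm)
    for (mth in grep("^qtl", methods, value = TRUE)) {
      ns <- as.integer(sub("qtl", "", mth))
      full_sel[[mth]] <- select_qtl(eff_full, map, n_select = ns,
                                    window = window)
    }
  }

  # near-equal fold sizes: cycle 1..k over a random permutation of the lines
  fold_of <- with_seed(seed, {
    perm <- sample(lines)
    setNames(rep(seq_len(k), length.out = length(perm)), perm)
  })
  fold_tbl <- tibble(line_id = names(fold_of), fold = as.integer(fold_of))

  preds <- purrr::map_dfr(seq_len(k), function(i) {
    val_lines <- names(fold_of)[fold_of == i]
    train <- trial %>% filter(!.data$line_id %in% val_lines)
    out <- list()
    gen_fit <- NULL
    if ("genomic" %in% methods || qtl_selection == "fold") {
      gen_fit <- fit_genomic(train, trait, grm, spatial = spatial,
                             use_blocks = use_blocks, control = control)
    }
    if ("genomic" %in% methods) {
      eff <- backsolve_marker_effects(gen_fit, M, grm)
      pv <- predict_new(M[val_lines, , drop = FALSE], eff)
      out$genomic <- pv %>% mutate(method = "genomic")
    }
    for (mth in grep("^qtl", methods, value = TRUE)) {
      ns <- as.integer(sub("qtl", "", mth))
      sel <- if (qtl_selection == "full") {
        full_sel[[mth]]
      } else {
        select_qtl(backsolve_marker_effects(gen_fit, M, grm), map,
                   n_select = ns, window = window)
      }
      qfit <- fit_qtl(train, trait, sel, M, spatial = spatial,
                      use_blocks = use_blocks, control = control)
      beta <- setNames(qfit$qtl_effects$beta, qfit$qtl_effects$marker)
      gh <- if (length(beta)) {
        as.vector(M[val_lines, names(beta), drop = FALSE] %*% beta)
      } else {
        rep(0, length(val_lines))
      }
      out[[mth]] <- tibble(line_id = val_lines, g_hat = gh, method = mth)
    }
    bind_rows(out) %>% mutate(fold = i)
  })

  accuracy <- preds %>%
    group_by(.data$method) %>%
    summarise(
      accuracy_additive = safe_cor(.data$g_hat, g_a_full[.data$line_id]),
      accuracy_total = safe_cor(.data$g_hat, g_t_full[.data$line_id]) /
        sqrt(H2_base),
      n_lines = dplyr::n(), .groups = "drop") %>%
    mutate(trait = trait)

  structure(list(accuracy = accuracy, predictions = preds,
                 folds = fold_tbl,
                 reference = list(genomic = glance(full_gen),
                                  baseline = glance(full_base)),
                 additive_proportion = full_gen$heritability$additive_proportion,
                 H2_baseline = H2_base, seed = seed, k = k,
                 qtl_selection = qtl_selection, trait = trait),
            class = "panel_cv")
}

safe_cor <- function(x, y) {
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
    inform("constant predictions or references: accuracy undefined (NA).")
    return(NA_real_)
  }
  cor(x, y)
}

#' @export
print.panel_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, trait `%s` (seed %d)\n",
              x$k, x$trait, x$seed))
  print(as.data.frame(x$accuracy), row.names = FALSE)
  invisible(x)
}

#' Tidy the accuracy table of a cross-validation result
#'
#' @param x A `panel_cv`.
#' @param ... Unused.
#' @return The per-method accuracy tibble with the trait's additive
#'   proportion attached.
#' @method tidy panel_cv
#' @export
tidy.panel_cv <- function(x, ...) {
  x$accuracy %>% mutate(additive_proportion = x$additive_proportion)
}

#' Accuracy comparison plot for a cross-validation result
#'
#' @param object A `panel_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_cv
#' @export
autoplot.panel_cv <- function(object, ...) {
  df <- object$accuracy %>%
    tidyr::pivot_longer(c("accuracy_additive", "accuracy_total"),
                        names_to = "measure", values_to = "accuracy") %>%
    mutate(measure = sub("accuracy_", "", .data$measure))
  ggplot(df, aes(x = .data$method, y = .data$accuracy, fill = .data$measure)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "prediction accuracy", fill = NULL,
         title = sprintf("trait %s", object$trait)) +
    theme_minimal()
}

#' Relate prediction accuracy to the additive proportion across traits
#'
#' Pearson correlations of the two cross-validation accuracy measures with
#' the percentage of genetic variance that is additive, across traits.
#' High-additivity traits lose least when predictions are scored against
#' total (rather than additive) genetic values, so `accuracy_total`
#' typically tracks the additive proportion strongly while
#' `accuracy_additive` does not.
#'
#' @param df Data frame with one row per trait: `accuracy_additive`,
#'   `accuracy_total`, `additive_proportion` (e.g. `tidy()` results of
#'   several [cross_validate()] runs for one method, or a published
#'   accuracy table).
#' @return Tibble: `measure`, `r`, `n_traits`.
#' @export
accuracy_vs_additivity <- function(df) {
  need <- c("accuracy_additive", "accuracy_total", "additive_proportion")
  if (!all(need %in% names(df))) {
    abort(sprintf("`df` needs columns %s.", paste(need, collapse = ", ")),
          class = "fieldblup_input_error")
  }
  if (nrow(df) < 3L) {
    abort("at least 3 traits are required.", class = "fieldblup_input_error")
  }
  r_of <- function(x) {
    if (sd(x) == 0 || sd(df$additive_proportion) == 0) {
      inform("constant values: correlation undefined (NA).")
      return(NA_real_)
    }
    cor(x, df$additive_proportion)
  }
  tibble(measure = c("total", "additive"),
         r = c(r_of(df$accuracy_total), r_of(df$accuracy_additive)),
         n_traits = nrow(df))
}
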