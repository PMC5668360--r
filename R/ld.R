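#' Pairwise linkage disequilibrium (r squared) within chromosomes
#'
#' For every intra-chromosomal marker pair within `max_separation` cM,
#' computes `r^2` as the squared Pearson correlation of the allele-code
#' columns over pairwise-complete lines. Because panel lines are inbred,
#' genotype correlation is the natural LD measure; no haplotype phasing is
#' involved. Pairs with fewer than `min_complete` complete lines or a
#' zero-variance column are skipped (with a notice).
#'
#' @param M Lines x markers genotype matrix.
#' @param map Map tibble; only markers present in both `M` and `map` are
#'   used.
#' @param max_separation Maximum cM separation of pairs retained.
#' @param lines Optional subset of line ids (germplasm subset); default all.
#' @param subset_label Label stored with the pairs (e.g. "full panel").
#' @param min_complete Minimum pairwise-complete lines for a pair.
#' @return Tibble: `marker1`, `marker2`, `chrom`, `sep_cM`, `r2`, `n`,
#'   `subset`.
#' @export
ld_r2 <- function(M, map, max_separation = Inf, lines = NULL,
                  subset_label = "all", min_complete = 30L) {
  validate_marker_matrix(M)
  validate_map(map)
  if (!is.null(lines)) {
    missing_lines <- setdiff(lines, rownames(M))
    if (length(missing_lines)) {
      abort("`lines` contains ids absent from the genotype matrix.",
            class = "fieldblup_input_error")
    }
    M <- M[lines, , drop = FALSE]
  }
  if (!nrow(M)) abort("empty line subset.", class = "fieldblup_input_error")
  map <- map %>% filter(.data$marker %in% colnames(M))
  if (!nrow(map)) {
    abort("no mapped markers present in the genotype matrix.",
          class = "fieldblup_input_error")
  }
  skipped <- 0L
  out <- purrr::map_dfr(split(map, map$chrom), function(mp) {
    mp <- mp %>% arrange(.data$pos)
    X <- M[, mp$marker, drop = FALSE]
    m <- ncol(X)
    if (m < 2L) return(NULL)
    cmplt <- !is.na(X)
    nmat <- crossprod(cmplt)                      # pairwise-complete counts
    suppressWarnings(cm <- cor(X, use = "pairwise.complete.obs"))
    pair <- which(upper.tri(cm), arr.ind = TRUE)
    sep <- mp$pos[pair[, 2L]] - mp$pos[pair[, 1L]]
    keep <- sep <= max_separation
    pair <- pair[keep, , drop = FALSE]
    sep <- sep[keep]
    r <- cm[pair]
    nn <- nmat[pair]
    ok <- is.finite(r) & nn >= min_complete
    skipped <<- skipped + sum(!ok)
    tibble(marker1 = mp$marker[pair[ok, 1L]],
           marker2 = mp$marker[pair[ok, 2L]],
           chrom = mp$chrom[1L],
           sep_cM = sep[ok],
           r2 = r[ok]^2,
           n = as.integer(nn[ok]))
  })
  if (skipped > 0L) {
    inform(sprintf("ld_r2: skipped %d pairs (zero variance or < %d complete lines).",
                   skipped, min_complete))
  }
  out$subset <- subset_label
  out
}

#' Default LD decay distance bins
#'
#' 2 cM steps to 20 cM, then 10 cM steps to `max_cM`: fine resolution where
#' LD decays fastest, coarse in the plateau.
#'
#' @param max_cM Upper edge of the last bin.
#' @return Numeric vector of bin edges starting at 0.
#' @export
ld_default_bins <- function(max_cM = 60) {
  unique(c(seq(0, 20, by = 2), seq(20, max_cM, by = 10)))
}

#' Summarise LD decay in distance bins
#'
#' Per distance bin (and germplasm subset): number of pairs, median and
#' quartiles of `r^2`, and Tukey whisker bounds (the most extreme values
#' within 1.5 IQR of the quartiles). Empty bins are emitted with `n = 0`.
#'
#' @param pairs Pair table from [ld_r2()].
#' @param bin_edges Bin edges in cM; must cover the observed separations.
#' @return Tibble: `subset`, `bin`, `lower_cM`, `upper_cM`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`.
#' @export
ld_decay_bins <- function(pairs, bin_edges = ld_default_bins()) {
  bin_edges <- sort(unique(bin_edges))
  if (nrow(pairs) && max(pairs$sep_cM) > max(bin_edges)) {
    abort("bin edges do not cover the observed separations.",
          class = "fieldblup_input_error")
  }
  labs <- sprintf("(%g,%g]", head(bin_edges, -1L), tail(bin_edges, -1L))
  labs[1L] <- sprintf("[%g,%g]", bin_edges[1L], bin_edges[2L])
  grid <- tidyr::expand_grid(subset = unique(pairs$subset) %||% "all",
                             bin = factor(labs, levels = labs))
  pairs %>%
    mutate(bin = cut(.data$sep_cM, breaks = bin_edges, labels = labs,
                     include.lowest = TRUE)) %>%
    group_by(.data$subset, .data$bin) %>%
    summarise(n = dplyr::n(),
              median = median(.data$r2),
              q1 = quantile(.data$r2, 0.25, names = FALSE),
              q3 = quantile(.data$r2, 0.75, names = FALSE),
              whisker_low = min(.data$r2[.data$r2 >=
                quantile(.data$r2, 0.25, names = FALSE) - 1.5 * stats::IQR(.data$r2)]),
              whisker_high = max(.data$r2[.data$r2 <=
                quantile(.data$r2, 0.75, names = FALSE) + 1.5 * stats::IQR(.data$r2)]),
              .groups = "drop") %>%
    dplyr::right_join(grid, by = c("subset", "bin")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           lower_cM = bin_edges[as.integer(.data$bin)],
           upper_cM = bin_edges[as.integer(.data$bin) + 1L]) %>%
    arrange(.data$subset, .data$bin) %>%
    select("subset", "bin", "lower_cM", "upper_cM", "n", "median",
           "q1", "q3", "whisker_low", "whisker_high")
}

#' Boxplot-style LD decay figure
#'
#' @param bins Output of [ld_decay_bins()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(bins) {
  ggplot(bins %>% filter(.data$n > 0),
         aes(x = .data$bin, group = .data$subset)) +
    geom_boxplot(aes(ymin = .data$whisker_low, lower = .data$q1,
                     middle = .data$median, upper = .data$q3,
                     ymax = .data$whisker_high, fill = .data$subset),
                 stat = "identity", alpha = 0.7) +
    labs(x = "marker separation (cM)", y = expression(r^2),
         fill = "subset") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
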