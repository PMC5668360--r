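#' Select putative QTL markers by greedy outlier-statistic search
#'
#' Iteratively picks the mapped marker with the largest outlier statistic,
#' then excludes every marker within `window` cM on either side of it on
#' the same chromosome, until `n_select` markers are chosen or the
#' candidate set is exhausted. Unmapped markers are never candidates. Ties
#' in `t` break to the lowest marker index (input order), making the
#' selection deterministic.
#'
#' @param effects A `marker_effects` tibble (needs `marker` and `t`).
#' @param map Map tibble giving chromosome and position for candidates.
#' @param n_select Number of markers requested (1 and 5 mirror the
#'   single-QTL and five-QTL prediction models).
#' @param window Exclusion half-window in cM (default 25).
#' @return A `qtl_selection` tibble: `marker`, `chrom`, `pos`, `t`,
#'   `order`; the returned count may be below `n_select` on exhaustion.
#' @export
#' @examples
#' eff <- tibble::tibble(marker = c("a", "b", "c", "d"),
#'                       t = c(5, 9, 7, 3))
#' map <- tibble::tibble(marker = c("a", "b", "c", "d"),
#'                       chrom = "1A", pos = c(0, 10, 30, 60))
#' select_qtl(eff, map, n_select = 2)$marker
select_qtl <- function(effects, map, n_select, window = 25) {
  validate_map(map)
  n_select <- check_count(n_select, "n_select")
  cand <- effects %>%
    mutate(.idx = dplyr::row_number()) %>%
    dplyr::inner_join(map, by = "marker")
  if (!nrow(cand)) {
    abort("no mapped markers among the candidates.",
          class = "fieldblup_input_error")
  }
  picked <- list()
  alive <- rep(TRUE, nrow(cand))
  for (s in seq_len(n_select)) {
    if (!any(alive)) break
    t_alive <- ifelse(alive, cand$t, -Inf)
    best <- which(t_alive == max(t_alive))[1L]  # tie -> lowest input index
    picked[[s]] <- cand[best, ]
    alive <- alive & !(cand$chrom == cand$chrom[best] &
                         abs(cand$pos - cand$pos[best]) <= window)
  }
  out <- bind_rows(picked) %>%
    mutate(order = dplyr::row_number()) %>%
    select("marker", "chrom", "pos", "t", "order")
  class(out) <- c("qtl_selection", class(out))
  attr(out, "window") <- window
  out
}
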