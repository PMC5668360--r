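#' Summarise a genetic map
#'
#' Per group: marker count, number of unique map positions, markers per
#' position (count / unique), genetic length (max - min position, cM) and
#' the mean interval between unique positions (length / (unique - 1)).
#' Aggregate groupings (genome, homoeologous group, total) pool lengths and
#' `(unique - 1)` interval counts across chromosomes, so the aggregate mean
#' interval is `sum(length) / sum(unique - 1)`. Genome and homoeologous
#' group are parsed from wheat-style chromosome labels (e.g. "3B" is genome
#' B, group 3) and skipped when labels do not follow that convention.
#'
#' @param map Map tibble (`marker`, `chrom`, `pos`).
#' @param grouping One or more of `"chromosome"`, `"genome"`,
#'   `"homoeologous_group"`, `"total"`.
#' @param digits Rounding applied to the derived ratio columns (the field's
#'   reporting convention is one ratio decimal and two interval decimals);
#'   `NULL` for no rounding.
#' @return Tibble with columns `group`, `level`, `n_markers`,
#'   `n_positions`, `markers_per_position`, `length_cM`, `mean_interval_cM`.
#' @export
summarize_map <- function(map,
                          grouping = c("chromosome", "genome",
                                       "homoeologous_group", "total"),
                          digits = NULL) {
  validate_map(map)
  grouping <- match.arg(grouping, several.ok = TRUE)
  wheatish <- all(grepl("^[0-9]+[A-Za-z]$", unique(map$chrom)))

  per_chrom <- map %>%
    group_by(level = .data$chrom) %>%
    summarise(n_markers = dplyr::n(),
              n_positions = dplyr::n_distinct(.data$pos),
              length_cM = max(.data$pos) - min(.data$pos),
              .groups = "drop")

  pool <- function(df, label) {
    df %>%
      summarise(level = dplyr::first(.data$lab),
                intervals = sum(.data$n_positions - 1L),
                n_markers = sum(.data$n_markers),
                n_positions = sum(.data$n_positions),
                length_cM = sum(.data$length_cM),
                .groups = "drop") %>%
      mutate(group = label)
  }

  out <- list()
  if ("chromosome" %in% grouping) {
    out$chromosome <- per_chrom %>%
      mutate(group = "chromosome", intervals = .data$n_positions - 1L)
  }
  if ("genome" %in% grouping && wheatish) {
    out$genome <- per_chrom %>%
      mutate(lab = sub("^[0-9]+", "", .data$level)) %>%
      group_by(.data$lab) %>%
      pool("genome")
  }
  if ("homoeologous_group" %in% grouping && wheatish) {
    out$group <- per_chrom %>%
      mutate(lab = sub("[A-Za-z]$", "", .data$level)) %>%
      group_by(.data$lab) %>%
      pool("homoeologous_group")
  }
  if ("total" %in% grouping) {
    out$total <- per_chrom %>%
      mutate(lab = "total") %>%
      group_by(.data$lab) %>%
      pool("total")
  }
  res <- bind_rows(out) %>%
    mutate(markers_per_position = .data$n_markers / .data$n_positions,
           mean_interval_cM = ifelse(.data$intervals > 0,
                                     .data$length_cM / .data$intervals,
                                     NA_real_)) %>%
    select("group", "level", "n_markers", "n_positions",
           "markers_per_position", "length_cM", "mean_interval_cM")
  if (!is.null(digits)) {
    res <- res %>%
      mutate(markers_per_position = round(.data$markers_per_position, digits[1L]),
             mean_interval_cM = round(.data$mean_interval_cM,
                                      if (length(digits) > 1L) digits[2L] else digits[1L]))
  }
  res
}

#' Map summary arithmetic from published per-chromosome counts
#'
#' Applies the same identities as [summarize_map()] (markers per position =
#' markers / positions; mean interval = length / (positions - 1); pooled
#' totals sum lengths and interval counts) to a table of per-chromosome
#' counts, e.g. a published consensus map summary, and appends the derived
#' total row.
#'
#' @param counts Data frame with columns `level`, `n_markers`,
#'   `n_positions`, `length_cM`.
#' @return Tibble in the [summarize_map()] layout.
#' @export
#' @examples
#' summarize_map_counts(data.frame(level = "1A", n_markers = 838,
#'                                 n_positions = 308, length_cM = 129))
summarize_map_counts <- function(counts) {
  need <- c("level", "n_markers", "n_positions", "length_cM")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns level, n_markers, n_positions, length_cM.",
          class = "fieldblup_input_error")
  }
  counts <- as_tibble(counts[need])
  per <- counts %>%
    mutate(group = "chromosome", intervals = .data$n_positions - 1L)
  tot <- counts %>%
    summarise(level = "total", intervals = sum(.data$n_positions - 1L),
              n_markers = sum(.data$n_markers),
              n_positions = sum(.data$n_positions),
              length_cM = sum(.data$length_cM)) %>%
    mutate(group = "total")
  bind_rows(per, tot) %>%
    mutate(markers_per_position = .data$n_markers / .data$n_positions,
           mean_interval_cM = ifelse(.data$intervals > 0,
                                     .data$length_cM / .data$intervals,
                                     NA_real_)) %>%
    select("group", "level", "n_markers", "n_positions",
           "markers_per_position", "length_cM", "mean_interval_cM")
}
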