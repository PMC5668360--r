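# Delimited-text readers and writers for the pipeline's canonical formats:
# genotypes as TSV (lines x markers, first column the line id, "NA" for
# missing), maps and trial tables as CSV.

#' Write / read a genotype matrix (tab-delimited)
#'
#' @param M Lines x markers matrix.
#' @param path File path.
#' @return `read_genotypes()` returns the matrix with a `coding`
#'   attribute; `write_genotypes()` returns `path` invisibly.
#' @export
write_genotypes <- function(M, path) {
  validate_marker_matrix(M)
  df <- tibble(line_id = rownames(M))
  df <- dplyr::bind_cols(df, as_tibble(M, .name_repair = "minimal"))
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_genotypes
#' @param coding Expected allele coding, checked cell-wise: `"pm1"`
#'   accepts values in `[-1, 1]`, `"01"` in `[0, 1]`.
#' @export
read_genotypes <- function(path, coding = c("pm1", "01")) {
  coding <- match.arg(coding)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1L] != "line_id") {
    abort("genotype file must start with a `line_id` column.",
          class = "fieldblup_parse_error")
  }
  ids <- as.character(df$line_id)
  M <- as.matrix(df[-1L])
  if (!is.numeric(M)) {
    bad <- which(!vapply(df[-1L], is.numeric, TRUE))[1L]
    abort(sprintf("non-numeric allele calls in column `%s`.",
                  names(df[-1L])[bad]), class = "fieldblup_parse_error")
  }
  rownames(M) <- ids
  lo <- if (coding == "pm1") -1 else 0
  bad <- which(!is.na(M) & (M < lo | M > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("allele code %g out of range for %s coding at line %s, marker %s.",
                  M[bad[1L, , drop = FALSE]], coding,
                  rownames(M)[bad[1L, 1L]], colnames(M)[bad[1L, 2L]]),
          class = "fieldblup_parse_error")
  }
  attr(M, "coding") <- coding
  validate_marker_matrix(M)
}

#' Write / read a genetic map (CSV)
#'
#' @param map Map tibble (`marker`, `chrom`, `pos`).
#' @param path File path.
#' @return `read_map()` returns the validated map tibble.
#' @export
write_map <- function(map, path) {
  validate_map(map)
  readr::write_csv(map[c("marker", "chrom", "pos")], path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(marker = "c", chrom = "c",
                                                 pos = "d"))
  validate_map(map)
  as_tibble(map)
}

#' Write / read a field-trial table (CSV)
#'
#' @param trial Trial tibble (`plot`, `row`, `range`, `line_id`, optional
#'   `block`/`is_check`, trait columns).
#' @param path File path.
#' @return `read_trial()` returns the validated trial tibble.
#' @export
write_trial <- function(trial, path) {
  readr::write_csv(trial, path)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  trial <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("row", "range", "line_id")
  if (!all(need %in% names(trial))) {
    abort("trial file needs columns row, range, line_id.",
          class = "fieldblup_parse_error")
  }
  dup <- duplicated(trial[c("row", "range")])
  if (any(dup)) {
    abort(sprintf("duplicated plot coordinate at data row %d.",
                  which(dup)[1L]), class = "fieldblup_parse_error")
  }
  as_tibble(trial)
}

#' Read a phenotype workbook-style table with mapped columns
#'
#' Reads a delimited phenotype table whose column names do not follow the
#' package convention, remapping them via `columns` (a named vector:
#' canonical name = file column). Columns not mentioned are carried over
#' as trait columns.
#'
#' @param path Delimited file (delimiter guessed from the extension:
#'   `.csv` comma, otherwise tab).
#' @param columns Named character vector mapping canonical columns (`row`,
#'   `range`, `line_id`, optionally `plot`, `is_check`, `block`) to file
#'   columns.
#' @return Validated trial tibble.
#' @export
read_phenotype_table <- function(path, columns = c(row = "row",
                                                   range = "range",
                                                   line_id = "line_id")) {
  rd <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- rd(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols)) {
    abort(sprintf("phenotype table lacks mapped columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "fieldblup_parse_error")
  }
  idx <- match(unname(columns), names(df))
  names(df)[idx] <- names(columns)
  if (!all(c("row", "range", "line_id") %in% names(df))) {
    abort("column mapping must cover row, range and line_id.",
          class = "fieldblup_parse_error")
  }
  as_tibble(df)
}

#' Raw per-trait summary of a trial table
#'
#' Mean and standard deviation of the raw phenotypes, the usual first
#' look at a trial before any modelling.
#'
#' @param trial Trial tibble.
#' @param traits Trait column names; default every numeric column other
#'   than the layout columns.
#' @return Tibble: `trait`, `n`, `mean`, `sd`.
#' @export
trait_raw_summary <- function(trial, traits = NULL) {
  layout <- c("plot", "row", "range", "block", "line_id", "is_check")
  if (is.null(traits)) {
    traits <- setdiff(names(trial)[vapply(trial, is.numeric, TRUE)], layout)
  }
  purrr::map_dfr(traits, function(tr) {
    x <- trial[[tr]]
    tibble(trait = tr, n = sum(!is.na(x)),
           mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  })
}
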