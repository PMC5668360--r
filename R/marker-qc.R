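#' Minor allele frequencies of a genotype matrix
#'
#' Allele frequencies are computed over non-missing calls, counting each
#' residual heterozygote as half a copy of each allele.
#'
#' @param M Lines x markers genotype matrix (codes -1/0/+1 or 0/0.5/1).
#' @return Tibble: `marker`, `maf`, `n_called`.
#' @export
marker_maf <- function(M) {
  validate_marker_matrix(M)
  coding01 <- identical(attr(M, "coding"), "01")
  p <- if (coding01) colMeans(M, na.rm = TRUE) else colMeans((M + 1) / 2, na.rm = TRUE)
  tibble(marker = colnames(M),
         maf = unname(pmin(p, 1 - p)),
         n_called = unname(colSums(!is.na(M))))
}

#' Filter markers on minor allele frequency
#'
#' Removes markers whose MAF is strictly below `threshold` (the default 1%
#' is the panel's QC rule); survivors keep their order.
#'
#' @param M Lines x markers genotype matrix.
#' @param threshold MAF below which a marker is dropped (strict `<`).
#' @return The filtered matrix; attribute `removed` is a tibble of the
#'   dropped markers and their MAF.
#' @export
#' @examples
#' M <- matrix(c(1, 1, 1, 1, -1, 1, 1, 1), 4, 2,
#'             dimnames = list(paste0("l", 1:4), c("mono", "poly")))
#' colnames(maf_filter(M, 0.01))
maf_filter <- function(M, threshold = 0.01) {
  check_fraction(threshold, "threshold", lo = 0, hi = 0.5)
  maf <- marker_maf(M)
  drop <- maf$maf < threshold
  if (all(drop)) {
    abort("all markers fall below the MAF threshold.",
          class = "fieldblup_empty_output_error")
  }
  out <- M[, !drop, drop = FALSE]
  attr(out, "coding") <- attr(M, "coding")
  attr(out, "removed") <- maf[drop, ]
  attr(out, "maf_threshold") <- threshold
  out
}

#' Assign unmapped markers to chromosomes using LD
#'
#' Each marker absent from the map is assigned the chromosome of the mapped
#' marker with which it shows the highest `r^2` (squared Pearson
#' correlation over pairwise-complete lines). Assignments whose best `r^2`
#' falls below `floor_r2` are flagged unassigned, as are zero-variance
#' columns.
#'
#' @param M Lines x markers genotype matrix.
#' @param map Map tibble covering the mapped subset of markers.
#' @param floor_r2 Minimum best-anchor `r^2` for an assignment.
#' @return Tibble: `marker`, `chrom`, `anchor`, `r2`, `assigned`.
#' @export
assign_unmapped <- function(M, map, floor_r2 = 0.1) {
  validate_marker_matrix(M)
  validate_map(map)
  mapped <- intersect(map$marker, colnames(M))
  if (!length(mapped)) {
    abort("no mapped markers present in the genotype matrix.",
          class = "fieldblup_input_error")
  }
  unmapped <- setdiff(colnames(M), mapped)
  if (!length(unmapped)) {
    return(tibble(marker = character(), chrom = character(),
                  anchor = character(), r2 = numeric(), assigned = logical()))
  }
  suppressWarnings(
    cm <- cor(M[, unmapped, drop = FALSE], M[, mapped, drop = FALSE],
              use = "pairwise.complete.obs")^2
  )
  chrom_of <- setNames(map$chrom, map$marker)
  res <- purrr::map_dfr(seq_along(unmapped), function(i) {
    r2 <- cm[i, ]
    if (all(is.na(r2))) {
      return(tibble(marker = unmapped[i], chrom = NA_character_,
                    anchor = NA_character_, r2 = NA_real_, assigned = FALSE))
    }
    best <- which.max(r2)
    ok <- r2[best] >= floor_r2
    tibble(marker = unmapped[i],
           chrom = if (ok) unname(chrom_of[mapped[best]]) else NA_character_,
           anchor = mapped[best], r2 = unname(r2[best]), assigned = ok)
  })
  n_un <- sum(!res$assigned)
  if (n_un > 0L) {
    inform(sprintf("assign_unmapped: %d markers left unassigned (best r2 < %g or zero variance).",
                   n_un, floor_r2))
  }
  res
}
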