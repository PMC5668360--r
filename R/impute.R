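#' K-nearest-neighbour genotype imputation
#'
#' Imputes each missing call from the inverse-distance-weighted average of
#' the line's calls at the `k` nearest markers. Markers are treated as
#' points with lines as dimensions: distances are root-mean-square
#' differences of standardized allele-code columns over pairwise-complete
#' lines, which keeps the metric insensitive to call-rate differences and
#' coding scale. When a map is supplied the matrix is processed in
#' chromosome subsets (mapped markers plus markers linked to the
#' chromosome by LD via [assign_unmapped()]), bounding memory the way the
#' full-array pipeline requires; markers assignable to no chromosome form a
#' final "unassigned" pool. Observed calls are never altered.
#'
#' @param M Lines x markers genotype matrix with missing calls.
#' @param map Optional map tibble driving chromosome subsetting.
#' @param k Number of neighbour markers (fewer are used when fewer exist).
#' @param eps Distance floor so exact-duplicate neighbours get finite
#'   weight and dominate the average.
#' @param floor_r2 Passed to [assign_unmapped()] when `map` is given.
#' @return The completed matrix (imputed entries may be fractional in
#'   `[-1, 1]`).
#' @export
knn_impute <- function(M, map = NULL, k = 10L, eps = 1e-6, floor_r2 = 0.1) {
  validate_marker_matrix(M)
  k <- check_count(k, "k")
  if (!anyNA(M)) return(M)
  groups <- if (is.null(map)) {
    list(colnames(M))
  } else {
    validate_map(map)
    cols <- colnames(M)
    chrom_of <- setNames(rep(NA_character_, length(cols)), cols)
    mapped <- intersect(map$marker, cols)
    chrom_of[mapped] <- map$chrom[match(mapped, map$marker)]
    if (length(setdiff(cols, mapped))) {
      asg <- assign_unmapped(M, map, floor_r2 = floor_r2)
      chrom_of[asg$marker[asg$assigned]] <- asg$chrom[asg$assigned]
    }
    split(cols, ifelse(is.na(chrom_of), "unassigned", chrom_of))
  }
  out <- M
  for (g in groups) {
    sub <- M[, g, drop = FALSE]
    if (!anyNA(sub)) next
    out[, g] <- knn_impute_block(sub, k = k, eps = eps)
  }
  coding <- attr(M, "coding")
  attributes(out) <- attributes(M)[c("dim", "dimnames")]
  attr(out, "coding") <- coding
  attr(out, "imputation") <- list(method = "knn", k = k, distance = "rms standardized",
                                  weights = "inverse distance", eps = eps)
  out
}

# One marker pool: all-pairs marker distances, then per-entry weighted mean.
knn_impute_block <- function(X, k, eps) {
  m <- ncol(X)
  Xs <- scale(X)                                # columnwise standardize, NA kept
  Xs[, attr(Xs, "scale") == 0 | is.na(attr(Xs, "scale"))] <- 0
  X0 <- Xs; X0[is.na(X0)] <- 0
  W <- (!is.na(Xs)) * 1
  # pairwise-complete mean squared difference between standardized columns
  ss <- crossprod(X0^2, W)
  cp <- crossprod(X0)
  nn <- crossprod(W)
  D2 <- (ss + t(ss) - 2 * cp) / pmax(nn, 1)
  D2[nn == 0] <- Inf
  D <- sqrt(pmax(D2, 0))
  diag(D) <- Inf
  miss <- which(is.na(X), arr.ind = TRUE)
  for (jj in unique(miss[, 2L])) {
    ord <- order(D[, jj])
    ord <- ord[is.finite(D[ord, jj])]
    rows <- miss[miss[, 2L] == jj, 1L]
    for (i in rows) {
      cand <- ord[!is.na(X[i, ord])]
      if (!length(cand)) { X[i, jj] <- mean(X[, jj], na.rm = TRUE); next }
      nb <- head(cand, k)
      w <- 1 / pmax(D[nb, jj], eps)
      X[i, jj] <- sum(w * X[i, nb]) / sum(w)
    }
  }
  X
}
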