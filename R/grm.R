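#' Build the scaled genomic relationship matrix
#'
#' Computes `G = M M'` from the complete allele-code matrix and rescales it
#' by `r = trace(G) / n` so the average self-relationship of `G_s = G / r`
#' is exactly 1. The matrix is not column-centred by default (the raw
#' cross-product of allele codes is the panel's definition); a
#' VanRaden-style column-centred alternative is available. The eigen
#' decomposition is computed once, used to flag positive definiteness, and
#' cached for the REML solver and marker-effect back-solving.
#'
#' @param M Complete lines x markers genotype matrix.
#' @param center Centre marker columns before the cross-product.
#' @param bend When the cross-product is singular (e.g. duplicate inbred
#'   lines, or fewer markers than lines), floor its eigenvalues at
#'   `bend_floor` times the largest so the matrix is invertible; the
#'   scaled matrix is reconstructed from the floored spectrum and
#'   `trace(G_s)/n = 1` restored.
#' @param bend_floor Relative eigenvalue floor used by `bend`.
#' @return A `grm` object: `G_s`, `r`, `n`, `eigenvalues`, `eigenvectors`,
#'   `positive_definite`, `bent`, `line_ids`, `marker_fingerprint`.
#' @export
#' @examples
#' M <- matrix(c(1, 1, -1, 1), 2, 2,
#'             dimnames = list(c("l1", "l2"), c("m1", "m2")))
#' build_grm(M)$G_s
build_grm <- function(M, center = FALSE, bend = FALSE, bend_floor = 1e-6) {
  validate_marker_matrix(M, allow_missing = FALSE)
  if (any(!is.finite(M))) {
    abort("genotype matrix contains non-finite entries.",
          class = "fieldblup_input_error")
  }
  if (center) M <- scale(M, center = TRUE, scale = FALSE)
  n <- nrow(M)
  G <- tcrossprod(M)
  r <- sum(diag(G)) / n
  if (r <= 0) {
    abort("trace of G is zero; no marker variation.",
          class = "fieldblup_input_error")
  }
  G_s <- G / r
  eig <- eigen(G_s, symmetric = TRUE)
  pd <- min(eig$values) > 1e-8 * max(eig$values)
  bent <- FALSE
  if (!pd && bend) {
    lam <- pmax(eig$values, bend_floor * max(eig$values))
    lam <- lam * n / sum(lam)           # restore trace(G_s)/n = 1
    G_s <- eig$vectors %*% (lam * Matrix::t(eig$vectors))
    dimnames(G_s) <- list(rownames(M), rownames(M))
    eig$values <- lam
    pd <- TRUE
    bent <- TRUE
  } else if (!pd) {
    warn(paste("G_s is singular or near-singular (duplicate or linearly",
               "dependent lines); genomic fits will refuse it. Drop",
               "duplicates or rebuild with bend = TRUE."))
  }
  structure(list(G_s = G_s, r = r, n = n,
                 eigenvalues = eig$values, eigenvectors = eig$vectors,
                 positive_definite = pd, bent = bent,
                 line_ids = rownames(M),
                 centered = center,
                 marker_fingerprint = fingerprint_markers(M)),
            class = "grm")
}

fingerprint_markers <- function(M) {
  c(n = nrow(M), p = ncol(M),
    s = sum(M) , s2 = sum(M^2))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Scaled genomic relationship matrix: %d lines, r = %.4f\n",
              x$n, x$r))
  cat(sprintf("  eigenvalues in [%.3g, %.3g]; positive definite: %s\n",
              min(x$eigenvalues), max(x$eigenvalues), x$positive_definite))
  invisible(x)
}
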