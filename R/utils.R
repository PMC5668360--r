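# Internal helpers shared across modules.

# AR1 correlation matrix, its analytic inverse (tridiagonal) and log-determinant.
ar1_mat <- function(n, rho) {
  stats::toeplitz(rho^(0:(n - 1)))
}

ar1_inv <- function(n, rho) {
  # (1 / (1 - rho^2)) * tridiag(-rho; 1, 1 + rho^2, ..., 1 + rho^2, 1)
  if (n == 1L) return(Matrix::Matrix(1, 1, 1, sparse = TRUE))
  d <- c(1, rep(1 + rho^2, n - 2L), 1) / (1 - rho^2)
  o <- rep(-rho / (1 - rho^2), n - 1L)
  Matrix::bandSparse(n, k = c(-1L, 0L, 1L), diagonals = list(o, d, o),
                     symmetric = FALSE)
}

ar1_logdet <- function(n, rho) (n - 1) * log(1 - rho^2)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "fieldblup_config_error")
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  bad <- length(x) != 1L || !is.finite(x) || x < lo || x > hi ||
    (open_hi && x >= hi)
  if (bad) {
    abort(sprintf("`%s` must be a number in [%g, %g%s.", name, lo, hi,
                  if (open_hi) ")" else "]"),
          class = "fieldblup_config_error")
  }
  as.numeric(x)
}

# Seeded evaluation that does not disturb the caller's RNG stream when an
# explicit seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

validate_marker_matrix <- function(M, allow_missing = TRUE, fractional = TRUE) {
  if (!is.matrix(M) || !is.numeric(M)) {
    abort("genotypes must be a numeric matrix (lines x markers).",
          class = "fieldblup_input_error")
  }
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    abort("genotype matrix needs line ids as rownames and marker names as colnames.",
          class = "fieldblup_input_error")
  }
  if (anyDuplicated(rownames(M)) || anyDuplicated(colnames(M))) {
    abort("duplicated line ids or marker names in genotype matrix.",
          class = "fieldblup_input_error")
  }
  vals <- M[!is.na(M)]
  if (!allow_missing && anyNA(M)) {
    abort("genotype matrix contains missing calls where none are allowed.",
          class = "fieldblup_input_error")
  }
  if (fractional) {
    if (any(vals < -1 - 1e-8 | vals > 1 + 1e-8)) {
      abort("allele codes must lie in [-1, +1].", class = "fieldblup_input_error")
    }
  } else if (!all(vals %in% c(-1, 0, 1))) {
    abort("allele codes must be -1, 0 or +1.", class = "fieldblup_input_error")
  }
  invisible(M)
}

validate_map <- function(map) {
  need <- c("marker", "chrom", "pos")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    abort("a genetic map needs columns marker, chrom, pos (cM).",
          class = "fieldblup_input_error")
  }
  if (anyDuplicated(map$marker)) {
    abort("duplicated marker names in genetic map.",
          class = "fieldblup_input_error")
  }
  if (any(!is.finite(map$pos)) || any(map$pos < 0)) {
    abort("map positions must be finite and >= 0.",
          class = "fieldblup_input_error")
  }
  invisible(map)
}
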