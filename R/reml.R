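# REML engine for the trial mixed models.
#
# All three model kinds share one covariance structure
#   H = sigma2 * (R + gamma_u Z Z' + Z_g Gamma_g Z_g')
# with R = AR1(rho_r) (x) AR1(rho_c) over the plot grid and
#   Gamma_g = gamma_t I                  (baseline: total genetic effect)
#   Gamma_g = gamma_a G_s + gamma_p I    (genomic: additive + residual)
#   Gamma_g = gamma_p I                  (QTL model: residual genetic only;
#                                         selected markers sit in X)
# The error variance sigma2 is profiled out analytically, so the optimiser
# works on variance ratios gamma and the two AR1 parameters only. The
# likelihood is evaluated through the mixed-model-equation (Woodbury)
# identities: R^-1 is the analytic tridiagonal AR1 inverse (Kronecker
# product, sparse) on complete grids and a dense Cholesky inverse otherwise,
# and G_s enters through its cached eigendecomposition so the genetic
# coefficient block is diagonal in rotated coordinates. The projection
# matrix P is never formed densely; BLUPs and their variance come from the
# same solves.

LOG2PI <- log(2 * pi)

#' Control parameters for the REML fits
#'
#' @param gamma_lower,gamma_upper Bounds for variance ratios
#'   (component / error variance); the lower bound acts as the boundary
#'   detection threshold.
#' @param rho_max Absolute bound for the AR1 parameters.
#' @param start_gamma,start_rho Starting values: every variance component
#'   starts at an equal share of the phenotypic variance (ratio 1) and the
#'   spatial parameters at 0.1.
#' @param tol Convergence tolerance on the log-likelihood and parameters.
#' @param maxit Iteration cap per optimiser stage.
#' @return A list of class `reml_control`.
#' @export
reml_control <- function(gamma_lower = 1e-8, gamma_upper = 1e6,
                         rho_max = 0.999, start_gamma = 1, start_rho = 0.1,
                         tol = 1e-6, maxit = 500L) {
  structure(list(gamma_lower = gamma_lower, gamma_upper = gamma_upper,
                 rho_max = rho_max, start_gamma = start_gamma,
                 start_rho = start_rho, tol = tol, maxit = maxit),
            class = "reml_control")
}

# ---- data assembly ---------------------------------------------------------

build_reml_data <- function(trial, trait, kind, grm = NULL, qtl_geno = NULL,
                            covariates = NULL, use_blocks = NULL,
                            spatial = TRUE) {
  need <- c("row", "range", "line_id")
  if (!is.data.frame(trial) || !all(need %in% names(trial))) {
    abort("trial table needs columns row, range, line_id.",
          class = "fieldblup_input_error")
  }
  if (!trait %in% names(trial)) {
    abort(sprintf("trait `%s` not found in trial table.", trait),
          class = "fieldblup_input_error")
  }
  keep <- !is.na(trial[[trait]])
  trial <- trial[keep, , drop = FALSE]
  if (anyDuplicated(trial[c("row", "range")])) {
    abort("duplicated plot coordinates in trial table.",
          class = "fieldblup_input_error")
  }
  ord <- order(trial$row, trial$range)
  trial <- trial[ord, , drop = FALSE]
  n <- nrow(trial)
  y <- as.numeric(trial[[trait]])

  lines <- sort(unique(trial$line_id))
  m <- length(lines)
  li <- match(trial$line_id, lines)
  Zg <- sparseMatrix(i = seq_len(n), j = li, x = 1, dims = c(n, m))

  use_blocks <- use_blocks %||% ("block" %in% names(trial))
  if (use_blocks && !"block" %in% names(trial)) {
    abort("`use_blocks = TRUE` but trial has no block column.",
          class = "fieldblup_input_error")
  }
  b <- 0L; Zb <- NULL
  if (use_blocks) {
    bl <- as.integer(factor(trial$block))
    b <- max(bl)
    Zb <- as.matrix(sparseMatrix(i = seq_len(n), j = bl, x = 1, dims = c(n, b)))
  }

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates %||% character()) {
    if (!cv %in% names(trial)) {
      abort(sprintf("covariate `%s` not in trial table.", cv),
            class = "fieldblup_input_error")
    }
    X <- cbind(X, scale(as.numeric(trial[[cv]]))[, 1L])
    colnames(X)[ncol(X)] <- cv
  }
  if (kind == "qtl" && !is.null(qtl_geno) && ncol(qtl_geno) > 0L) {
    idx <- match(trial$line_id, rownames(qtl_geno))
    if (anyNA(idx)) {
      abort("selected marker genotypes missing for some trial lines.",
            class = "fieldblup_input_error")
    }
    Q <- qtl_geno[idx, , drop = FALSE]
    colnames(Q) <- colnames(qtl_geno)
    X <- cbind(X, Q)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    warn(sprintf("dropping aliased fixed-effect columns: %s",
                 paste(dropped, collapse = ", ")))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }

  U <- NULL; lam <- rep(1, m)
  if (kind == "genomic") {
    if (is.null(grm) || !inherits(grm, "grm")) {
      abort("genomic fits need a `grm` object from build_grm().",
            class = "fieldblup_input_error")
    }
    pos <- match(lines, grm$line_ids)
    if (anyNA(pos)) {
      abort("GRM does not cover all trial lines.",
            class = "fieldblup_input_error")
    }
    if (!grm$positive_definite) {
      abort(paste("G_s is not positive definite; jitter or bend the GRM",
                  "(e.g. drop duplicate lines) before fitting."),
            class = "fieldblup_input_error")
    }
    if (length(pos) == grm$n && all(pos == seq_len(grm$n))) {
      U <- grm$eigenvectors
      lam <- grm$eigenvalues
      Gsub <- grm$G_s
    } else {
      Gsub <- grm$G_s[pos, pos, drop = FALSE]
      eig <- eigen(Gsub, symmetric = TRUE)
      U <- eig$vectors
      lam <- pmax(eig$values, 1e-12)
    }
  } else {
    Gsub <- NULL
  }
  ZgU <- if (is.null(U)) as.matrix(Zg) else as.matrix(Zg %*% U)

  rows <- trial$row; cols <- trial$range
  ur <- sort(unique(rows)); uc <- sort(unique(cols))
  complete <- length(ur) * length(uc) == n &&
    all(diff(ur) == 1) && all(diff(uc) == 1)
  # complete-grid row-major index check: after the (row, range) sort the
  # plot order must be exactly row-major for the Kronecker form to apply
  if (complete) {
    ri <- match(rows, ur); ci <- match(cols, uc)
    complete <- all((ri - 1L) * length(uc) + ci == seq_len(n))
  }

  list(trial = trial, y = y, X = X, Zb = Zb, Zg = Zg, ZgU = ZgU, U = U,
       lam = lam, Gsub = Gsub, lines = lines, n = n, b = b, m = m,
       p = ncol(X), kind = kind, rows = rows, cols = cols,
       nr = length(ur), nc = length(uc), complete = complete,
       spatial = spatial, grm = grm,
       fingerprint = c(n = n, sy = sum(y), sy2 = sum(y^2)))
}

# R^-1 (and log|R|) for the current AR1 parameters.
ri_for_rho <- function(dat, rho_r, rho_c) {
  if (!dat$spatial || (rho_r == 0 && rho_c == 0)) {
    return(list(Ri = Diagonal(dat$n), ldetR = 0))
  }
  if (dat$complete) {
    Ri <- kronecker(ar1_inv(dat$nr, rho_r), ar1_inv(dat$nc, rho_c))
    ldetR <- dat$nc * ar1_logdet(dat$nr, rho_r) +
      dat$nr * ar1_logdet(dat$nc, rho_c)
  } else {
    R <- rho_r^abs(outer(dat$rows, dat$rows, "-")) *
      rho_c^abs(outer(dat$cols, dat$cols, "-"))
    ch <- chol(R)
    Ri <- chol2inv(ch)
    ldetR <- 2 * sum(log(diag(ch)))
  }
  list(Ri = Ri, ldetR = ldetR)
}

# Cross-products of [X, Zb, ZgU, y] against R^-1, cached per rho pair.
rho_products <- function(dat, rho_r, rho_c, cache) {
  key <- sprintf("%.15g_%.15g", rho_r, rho_c)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ri <- ri_for_rho(dat, rho_r, rho_c)
  Fmat <- cbind(dat$X, dat$Zb, dat$ZgU, dat$y)
  RiF <- as.matrix(ri$Ri %*% Fmat)
  out <- list(BigG = crossprod(Fmat, RiF), ldetR = ri$ldetR,
              Ri = ri$Ri, RiF = RiF)
  if (length(cache) > 4L) rm(list = ls(cache)[1L], envir = cache)
  cache[[key]] <- out
  out
}

# Core evaluation. gamma: named list(u = , a = , p = , t = ) as applicable.
# Returns -2 logL (profiled over sigma2 unless sigma2 given), or +Inf on a
# rejected (non-PD) point; with details = TRUE returns the solve by-products.
reml_eval <- function(dat, gamma, rho_r, rho_c, cache, sigma2 = NULL,
                      details = FALSE) {
  rp <- tryCatch(rho_products(dat, rho_r, rho_c, cache),
                 error = function(e) NULL)
  if (is.null(rp)) return(Inf)
  BigG <- rp$BigG
  p <- dat$p; b <- dat$b; m <- dat$m; n <- dat$n
  ix <- seq_len(p)
  iz <- if (b > 0L) p + seq_len(b) else integer()
  ig <- p + b + seq_len(m)
  iy <- p + b + m + 1L

  D_g <- switch(dat$kind,
    baseline = rep(gamma$t, m),
    genomic  = gamma$a * dat$lam + gamma$p,
    qtl      = rep(gamma$p, m))
  if (any(D_g <= 0)) return(Inf)
  dpre <- if (b > 0L) c(rep(1 / gamma$u, b), 1 / D_g) else 1 / D_g
  iw <- c(iz, ig)
  S <- BigG[iw, iw, drop = FALSE]
  diag(S) <- diag(S) + dpre
  cholS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cholS)) return(Inf)

  WRy <- BigG[iw, iy]
  WRX <- BigG[iw, ix, drop = FALSE]
  uy <- backsolve(cholS, backsolve(cholS, WRy, transpose = TRUE))
  uX <- backsolve(cholS, backsolve(cholS, WRX, transpose = TRUE))
  yHy <- BigG[iy, iy] - sum(WRy * uy)
  XHy <- BigG[ix, iy] - crossprod(WRX, uy)
  XHX <- BigG[ix, ix, drop = FALSE] - crossprod(WRX, uX)
  cholXHX <- tryCatch(chol((XHX + t(XHX)) / 2), error = function(e) NULL)
  if (is.null(cholXHX)) return(Inf)
  beta <- backsolve(cholXHX, backsolve(cholXHX, XHy, transpose = TRUE))
  yPy <- yHy - sum(XHy * beta)
  if (!is.finite(yPy) || yPy <= 0) return(Inf)

  ldetGamma <- sum(log(D_g)) + if (b > 0L) b * log(gamma$u) else 0
  ldetS <- 2 * sum(log(diag(cholS)))
  ldetXHX <- 2 * sum(log(diag(cholXHX)))
  np <- n - p
  if (is.null(sigma2)) {
    s2 <- yPy / np
    m2ll <- np * (log(s2) + 1 + LOG2PI) + rp$ldetR + ldetGamma + ldetS + ldetXHX
  } else {
    s2 <- sigma2
    m2ll <- np * (log(s2) + LOG2PI) + yPy / s2 +
      rp$ldetR + ldetGamma + ldetS + ldetXHX
  }
  if (!details) return(m2ll)
  list(m2ll = m2ll, s2 = s2, beta = as.vector(beta), uy = uy, uX = uX,
       cholS = cholS, cholXHX = cholXHX, XHy = XHy, BigG = BigG,
       Ri = rp$Ri, RiF = rp$RiF, iw = iw, ix = ix, ig = ig, iy = iy,
       D_g = D_g, yPy = yPy)
}

# Parameter vector <-> transformed optimiser scale.
theta_pack <- function(dat, control) {
  gn <- switch(dat$kind, baseline = "t", genomic = c("a", "p"), qtl = "p")
  if (dat$b > 0L) gn <- c("u", gn)
  list(gamma_names = gn,
       n_gamma = length(gn),
       est_rho = dat$spatial,
       lower = c(rep(log(control$gamma_lower), length(gn)),
                 if (dat$spatial) rep(-atanh(control$rho_max), 2L)),
       upper = c(rep(log(control$gamma_upper), length(gn)),
                 if (dat$spatial) rep(atanh(control$rho_max), 2L)),
       start = c(rep(log(control$start_gamma), length(gn)),
                 if (dat$spatial) rep(atanh(control$start_rho), 2L)))
}

theta_unpack <- function(theta, pack) {
  g <- as.list(exp(theta[seq_len(pack$n_gamma)]))
  names(g) <- pack$gamma_names
  if (pack$est_rho) {
    rr <- tanh(theta[pack$n_gamma + 1L])
    rc <- tanh(theta[pack$n_gamma + 2L])
  } else {
    rr <- rc <- 0
  }
  list(gamma = g, rho_r = rr, rho_c = rc)
}

reml_optimize <- function(dat, control) {
  pack <- theta_pack(dat, control)
  cache <- new.env(parent = emptyenv())
  nev <- 0L
  obj <- function(theta) {
    nev <<- nev + 1L
    pr <- theta_unpack(theta, pack)
    val <- reml_eval(dat, pr$gamma, pr$rho_r, pr$rho_c, cache)
    if (!is.finite(val)) val <- 1e10
    val
  }
  if (length(pack$start) == 1L) {
    fit1 <- NULL
    fit2 <- optim(pack$start, obj, method = "Brent",
                  lower = pack$lower, upper = pack$upper,
                  control = list(maxit = control$maxit))
  } else {
    fit1 <- tryCatch(
      optim(pack$start, obj, method = "L-BFGS-B",
            lower = pack$lower, upper = pack$upper,
            control = list(maxit = control$maxit, factr = 1e7)),
      error = function(e) NULL)
    start2 <- if (is.null(fit1)) pack$start else fit1$par
    fit2 <- optim(start2, obj, method = "Nelder-Mead",
                  control = list(maxit = if (is.null(fit1)) 2000L else 300L,
                                 reltol = 1e-9))
    fit2$par <- pmin(pmax(fit2$par, pack$lower), pack$upper)
  }
  best <- if (!is.null(fit1) && fit1$value <= fit2$value) fit1 else fit2
  pr <- theta_unpack(best$par, pack)
  det <- reml_eval(dat, pr$gamma, pr$rho_r, pr$rho_c, cache, details = TRUE)
  if (!is.list(det)) {
    abort("REML did not reach an admissible optimum; see convergence trace.",
          class = "fieldblup_convergence_error")
  }
  boundary <- names(which(vapply(pr$gamma, function(g)
    g <= control$gamma_lower * (1 + 1e-6), TRUE)))
  list(par = best$par, pack = pack, gamma = pr$gamma,
       rho_r = pr$rho_r, rho_c = pr$rho_c, details = det,
       logL = -det$m2ll / 2, n_eval = nev,
       convergence = (if (is.null(fit1)) 1L else fit1$convergence) +
         fit2$convergence,
       boundary = boundary, cache = cache)
}

#' Evaluate the REML log-likelihood at given variance components
#'
#' Exact restricted log-likelihood of the baseline, genomic or QTL trial
#' model at user-supplied variance components, on the same constant
#' (including the `(n - p) log 2 pi / 2` term) as the fitted models, so
#' values are directly comparable across models and against independent
#' dense-matrix computations.
#'
#' @param trial Trial tibble (`row`, `range`, `line_id`, optional `block`,
#'   trait columns).
#' @param trait Name of the trait column.
#' @param components Named list: `sigma2` (error variance, required),
#'   `rho_r`, `rho_c` (default 0), and `sigma2_u` (blocks; required when a
#'   block term is used) plus `sigma2_t` (baseline) or `sigma2_a` and
#'   `sigma2_p` (genomic) or `sigma2_p` (QTL).
#' @param kind Model kind.
#' @param grm [build_grm()] result (genomic kind).
#' @param qtl_geno Lines x selected-markers matrix (QTL kind).
#' @param covariates Optional trial columns entering X as standardized
#'   linear covariates.
#' @param use_blocks Include the iid block term (default: when a `block`
#'   column exists).
#' @return The REML log-likelihood (a single number).
#' @export
reml_loglik <- function(trial, trait, components,
                        kind = c("baseline", "genomic", "qtl"),
                        grm = NULL, qtl_geno = NULL, covariates = NULL,
                        use_blocks = NULL) {
  kind <- match.arg(kind)
  dat <- build_reml_data(trial, trait, kind, grm = grm, qtl_geno = qtl_geno,
                         covariates = covariates, use_blocks = use_blocks,
                         spatial = TRUE)
  s2 <- components$sigma2
  if (is.null(s2) || s2 <= 0) {
    abort("`components$sigma2` must be a positive error variance.",
          class = "fieldblup_input_error")
  }
  gamma <- list()
  if (dat$b > 0L) {
    if (is.null(components$sigma2_u)) {
      abort("block term present: supply `components$sigma2_u`.",
            class = "fieldblup_input_error")
    }
    gamma$u <- components$sigma2_u / s2
  }
  gamma <- switch(kind,
    baseline = c(gamma, list(t = components$sigma2_t / s2)),
    genomic  = c(gamma, list(a = components$sigma2_a / s2,
                             p = components$sigma2_p / s2)),
    qtl      = c(gamma, list(p = components$sigma2_p / s2)))
  if (any(!is.finite(unlist(gamma))) || any(unlist(gamma) <= 0)) {
    abort("variance components must be positive and finite.",
          class = "fieldblup_input_error")
  }
  cache <- new.env(parent = emptyenv())
  m2ll <- reml_eval(dat, gamma, components$rho_r %||% 0,
                    components$rho_c %||% 0, cache, sigma2 = s2)
  if (!is.finite(m2ll)) {
    abort("covariance not positive definite at the supplied components.",
          class = "fieldblup_input_error")
  }
  -m2ll / 2
}
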