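# REML engine: dense-oracle agreement, closed forms, heritabilities,
# model comparison.

test_that("structured REML log-likelihood equals the dense oracle", {
  pan <- tiny_panel()
  comp_sets <- list(
    list(sigma2 = 0.5, sigma2_u = 0.2, sigma2_a = 1, sigma2_p = 0.3,
         rho_r = 0.3, rho_c = 0.2),
    list(sigma2 = 1.2, sigma2_u = 0.05, sigma2_a = 0.4, sigma2_p = 0.8,
         rho_r = -0.4, rho_c = 0.55),
    list(sigma2 = 0.9, sigma2_u = 0.4, sigma2_a = 2, sigma2_p = 0.1,
         rho_r = 0, rho_c = 0))
  for (comp in comp_sets) {
    ll <- reml_loglik(pan$trial, "y", comp, kind = "genomic", grm = pan$grm)
    Gs <- pan$grm$G_s
    dimnames(Gs) <- list(pan$grm$line_ids, pan$grm$line_ids)
    ll_dense <- dense_reml_loglik(pan$trial, "y", comp, Gs = Gs,
                                  kind = "genomic")
    expect_equal(ll, ll_dense, tolerance = 1e-9)
  }
  # baseline kind
  compb <- list(sigma2 = 0.5, sigma2_u = 0.2, sigma2_t = 1.1,
                rho_r = 0.25, rho_c = -0.1)
  expect_equal(
    reml_loglik(pan$trial, "y", compb, kind = "baseline"),
    dense_reml_loglik(pan$trial, "y", compb, kind = "baseline"),
    tolerance = 1e-9)
})

test_that("log-likelihood collapses and scales as theory dictates", {
  pan <- tiny_panel()
  comp <- list(sigma2 = 0.7, sigma2_u = 0.15, sigma2_a = 0.9, sigma2_p = 0.2,
               rho_r = 0, rho_c = 0)
  # rho = 0 equals an independent-error evaluation (R = I) by construction
  ll0 <- reml_loglik(pan$trial, "y", comp, kind = "genomic", grm = pan$grm)
  Gs <- pan$grm$G_s
  dimnames(Gs) <- list(pan$grm$line_ids, pan$grm$line_ids)
  expect_equal(ll0, dense_reml_loglik(pan$trial, "y", comp, Gs = Gs),
               tolerance = 1e-9)

  # scaling y and all variances by c^2 shifts logL by -(n - p) log c
  cc <- 2.5
  trial2 <- pan$trial
  trial2$y <- trial2$y * cc
  comp2 <- lapply(comp, function(v) v * cc^2)
  comp2$rho_r <- comp$rho_r; comp2$rho_c <- comp$rho_c
  ll2 <- reml_loglik(trial2, "y", comp2, kind = "genomic", grm = pan$grm)
  n <- sum(!is.na(pan$trial$y)); p <- 1
  expect_equal(ll2 - ll0, -(n - p) * log(cc), tolerance = 1e-8)
})

test_that("balanced two-replicate REML matches the one-way ANOVA closed form", {
  set.seed(41)
  n_g <- 30
  g_eff <- rnorm(n_g, sd = sqrt(2))
  trial <- tibble::tibble(
    row = rep(1:n_g, each = 2), range = rep(1:2, n_g),
    line_id = rep(sprintf("g%02d", 1:n_g), each = 2),
    y = rep(g_eff, each = 2) + rnorm(2 * n_g, sd = 1))
  fit <- fit_baseline(trial, "y", use_blocks = FALSE, spatial = FALSE)
  a <- stats::anova(stats::aov(y ~ line_id, data = trial))
  msb <- a[["Mean Sq"]][1]; msw <- a[["Mean Sq"]][2]
  expect_equal(fit$components$sigma2, msw, tolerance = 1e-5)
  expect_equal(fit$components$sigma2_t, max((msb - msw) / 2, 0),
               tolerance = 1e-4)
})

test_that("pure-noise phenotypes drive the genetic variance to the boundary", {
  # replicated layout so sigma2_t is well informed; noise-only phenotypes.
  # the estimate piles up at (or near) zero, so judge it on a small average
  n_g <- 40; reps <- 4
  h2s <- vapply(1:5, function(s) {
    set.seed(55 + s)
    trial <- tibble::tibble(
      row = rep(seq_len(n_g), each = reps), range = rep(seq_len(reps), n_g),
      line_id = rep(sprintf("g%02d", seq_len(n_g)), each = reps),
      y = rnorm(n_g * reps))
    fit <- fit_baseline(trial, "y", use_blocks = FALSE, spatial = FALSE)
    # the REML solution must coincide with the truncated ANOVA estimator
    a <- stats::anova(stats::aov(y ~ line_id, data = trial))
    st <- max((a[["Mean Sq"]][1] - a[["Mean Sq"]][2]) / reps, 0)
    expect_equal(heritability(fit)$H2, st / (st + a[["Mean Sq"]][2]),
                 tolerance = 1e-4)
    heritability(fit)$H2
  }, 0)
  expect_lt(mean(h2s), 0.15)
})

test_that("an identity GRM collapses the genomic model onto the baseline", {
  pan <- tiny_panel()
  n <- pan$config$n_lines
  ids <- rownames(pan$geno)
  grm_id <- structure(list(G_s = diag(n), r = 1, n = n,
                           eigenvalues = rep(1, n),
                           eigenvectors = diag(n),
                           positive_definite = TRUE, line_ids = ids,
                           centered = FALSE,
                           marker_fingerprint = c(1, 2, 3, 4)),
                      class = "grm")
  fb <- fit_baseline(pan$trial, "y")
  fg <- fit_genomic(pan$trial, "y", grm_id)
  expect_equal(fg$logL, fb$logL, tolerance = 1e-6)
  expect_equal(fg$components$sigma2_a + fg$components$sigma2_p,
               fb$components$sigma2_t, tolerance = 1e-2)
})

test_that("BLUPs match the dense projection-matrix expressions", {
  pan <- tiny_panel()
  fg <- fit_genomic(pan$trial, "y", pan$grm)
  Gs <- pan$grm$G_s
  dimnames(Gs) <- list(pan$grm$line_ids, pan$grm$line_ids)
  dp <- dense_P(pan$trial, "y", fg$components, Gs)
  ga <- fg$components$sigma2_a * Gs[dp$lines, dp$lines] %*%
    t(dp$Zg) %*% dp$P %*% dp$y
  gp <- fg$components$sigma2_p * t(dp$Zg) %*% dp$P %*% dp$y
  expect_equal(fg$blup$g_a, as.vector(ga), tolerance = 1e-8)
  expect_equal(fg$blup$g_p, as.vector(gp), tolerance = 1e-8)
  expect_identical(fg$blup$line_id, dp$lines)
})

test_that("replicated lines shrink less than unreplicated lines", {
  pan <- small_panel()
  fb <- small_fit_baseline()
  trial <- pan$trial
  raw_dev <- tapply(trial$y, trial$line_id, mean) - mean(trial$y)
  shrink <- fb$blup$g_t / raw_dev[fb$blup$line_id]
  check <- trial$line_id[trial$is_check][1]
  is_check_line <- fb$blup$line_id == check
  expect_gt(shrink[is_check_line], median(shrink[!is_check_line]))
})

test_that("heritability formulas are applied verbatim", {
  fake <- function(kind, comp) {
    st <- if (kind == "genomic") comp$sigma2_a + comp$sigma2_p else comp$sigma2_t
    structure(list(kind = kind, trait = "y", components = comp,
                   heritability = if (kind == "genomic") {
                     list(H2 = st / (st + comp$sigma2),
                          h2 = comp$sigma2_a / (st + comp$sigma2),
                          additive_proportion = 100 * comp$sigma2_a / st)
                   } else {
                     list(H2 = st / (st + comp$sigma2), h2 = NA_real_,
                          additive_proportion = NA_real_)
                   }),
              class = "panel_fit")
  }
  h <- heritability(fake("genomic", list(sigma2_a = 3, sigma2_p = 1,
                                         sigma2 = 1)))
  expect_equal(h$H2, 0.8)
  expect_equal(h$h2, 0.6)
  expect_equal(h$additive_proportion, 75)

  hb <- heritability(fake("baseline", list(sigma2_t = 1, sigma2 = 1)))
  expect_equal(hb$H2, 0.5)

  h0 <- heritability(fake("genomic", list(sigma2_a = 2, sigma2_p = 0,
                                          sigma2 = 0.5)))
  expect_equal(h0$h2, h0$H2)
})

test_that("fit comparison reports the relative log-likelihood gain", {
  expect_equal(pct_improvement(-100, -50), 50)
  expect_equal(pct_improvement(-100, -100), 0)
  expect_equal(pct_improvement(25269, 26160), 100 * 891 / 25269)

  fb <- small_fit_baseline()
  fg <- small_fit_genomic()
  cmp <- compare_fits(fb, fg)
  expect_gt(cmp$delta_logL, 0)   # the additive partition must fit better
  expect_equal(cmp$pct_improvement,
               100 * (fg$logL - fb$logL) / abs(fb$logL))

  # mismatched data are rejected
  pan <- small_panel()
  trial2 <- pan$trial
  trial2$y <- trial2$y + 1
  fb2 <- fit_baseline(trial2, "y")
  expect_error(compare_fits(fb2, fg), class = "fieldblup_input_error")
})

test_that("tidy and glance expose components and summaries", {
  fg <- small_fit_genomic()
  td <- tidy(fg)
  expect_true(all(c("sigma2", "sigma2_a", "sigma2_p", "rho_r", "rho_c") %in%
                    td$component))
  gl <- glance(fg)
  expect_equal(gl$kind, "genomic")
  expect_true(gl$H2 >= 0 && gl$H2 <= 1)
  expect_true(gl$h2 <= gl$H2)
})
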