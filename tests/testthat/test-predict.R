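# Marker-effect back-solving, QTL selection, QTL models, cross-validation.

test_that("back-solved marker effects satisfy the algebraic identity", {
  pan <- small_panel()
  fg <- small_fit_genomic()
  eff <- backsolve_marker_effects(fg, pan$geno, pan$grm)
  lhs <- pan$geno[fg$blup$line_id, ] %*% eff$effect
  rhs <- pan$grm$r * fg$blup$g_a
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
  expect_true(all(eff$t >= 0))
  expect_equal(nrow(eff), ncol(pan$geno))

  # fingerprint guard
  expect_error(backsolve_marker_effects(fg, pan$geno[, -1], pan$grm),
               class = "fieldblup_input_error")
})

test_that("marker-effect variances match the dense projection oracle", {
  pan <- tiny_panel()
  fg <- fit_genomic(pan$trial, "y", pan$grm)
  eff <- backsolve_marker_effects(fg, pan$geno, pan$grm)
  Gs <- pan$grm$G_s
  dimnames(Gs) <- list(pan$grm$line_ids, pan$grm$line_ids)
  dp <- dense_P(pan$trial, "y", fg$components, Gs)
  Msub <- pan$geno[dp$lines, ]
  gm_dense <- fg$components$sigma2_a * t(Msub) %*% t(dp$Zg) %*% dp$P %*% dp$y
  expect_equal(eff$effect, as.vector(gm_dense), tolerance = 1e-8)
  T_dense <- t(dp$Zg) %*% dp$P %*% dp$Zg
  var_dense <- fg$components$sigma2_a^2 *
    diag(t(Msub) %*% T_dense %*% Msub)
  expect_equal(eff$var, as.vector(var_dense), tolerance = 1e-7)
})

test_that("outlier statistics are elementwise ratios with flagged zeros", {
  eff <- tibble::tibble(marker = c("a", "b", "c"),
                        effect = c(0, 2, 1), var = c(1, 4, 0))
  out <- outlier_statistics(eff)
  expect_equal(out$t, c(0, 1, 0))
  expect_true(out$flagged[3])
  neg <- tibble::tibble(marker = "d", effect = 1, var = -1e-9)
  expect_warning(outn <- outlier_statistics(neg), "clipped")
  expect_true(outn$flagged)
})

test_that("predictions of new lines are pure matrix products", {
  pan <- small_panel()
  fg <- small_fit_genomic()
  eff <- backsolve_marker_effects(fg, pan$geno, pan$grm)
  one <- pan$geno[3, , drop = FALSE]
  pv <- predict_new(one, eff)
  expect_equal(pv$g_hat, pan$grm$r * fg$blup$g_a[fg$blup$line_id ==
                                                   rownames(one)],
               tolerance = 1e-6)
  # duplicated rows duplicate predictions; zero effects predict zero
  two <- pan$geno[c(3, 3), , drop = FALSE]
  expect_equal(predict_new(two, eff)$g_hat, rep(pv$g_hat, 2))
  eff0 <- eff; eff0$effect <- 0
  expect_true(all(predict_new(one, eff0)$g_hat == 0))
  expect_error(predict_new(one[, -1, drop = FALSE], eff),
               class = "fieldblup_input_error")
})

test_that("greedy QTL selection honours the exclusion window and ties", {
  map <- tibble::tibble(marker = c("a", "b", "c", "d"), chrom = "1A",
                        pos = c(0, 10, 30, 60))
  eff <- tibble::tibble(marker = map$marker, t = c(5, 9, 7, 3))
  sel <- select_qtl(eff, map, n_select = 2, window = 25)
  expect_identical(sel$marker, c("b", "d"))

  # window exhaustion: five co-located markers yield a single pick
  map5 <- tibble::tibble(marker = letters[1:5], chrom = "2B",
                         pos = c(0, 5, 10, 15, 20))
  eff5 <- tibble::tibble(marker = letters[1:5], t = c(1, 2, 5, 2, 1))
  expect_equal(nrow(select_qtl(eff5, map5, n_select = 5, window = 25)), 1)

  # ties break to the lowest input index, deterministically
  efft <- tibble::tibble(marker = letters[1:5], t = c(3, 5, 5, 5, 1))
  selt <- select_qtl(efft, map5 %>% dplyr::mutate(pos = c(0, 30, 60, 90, 120)),
                     n_select = 2, window = 25)
  expect_identical(selt$marker[1], "b")
})

test_that("greedy selection matches brute-force enumeration on small maps", {
  brute <- function(t, chrom, pos, n_sel, window) {
    picked <- integer()
    alive <- rep(TRUE, length(t))
    for (s in seq_len(n_sel)) {
      if (!any(alive)) break
      cand <- which(alive)
      best <- cand[order(-t[cand], cand)][1]
      picked <- c(picked, best)
      alive <- alive & !(chrom == chrom[best] &
                           abs(pos - pos[best]) <= window)
    }
    picked
  }
  set.seed(99)
  for (rep in 1:25) {
    m <- sample(4:10, 1)
    map <- tibble::tibble(marker = paste0("m", 1:m),
                          chrom = sample(c("1A", "1B"), m, TRUE),
                          pos = round(runif(m, 0, 120), 1))
    tt <- round(runif(m, 0, 10), 2)
    eff <- tibble::tibble(marker = map$marker, t = tt)
    ns <- sample(1:4, 1)
    sel <- select_qtl(eff, map, n_select = ns, window = 25)
    expect_identical(sel$marker, map$marker[brute(tt, map$chrom, map$pos,
                                                  ns, 25)])
  }
})

test_that("selection is invariant to marker input order up to ties", {
  pan <- small_panel()
  fg <- small_fit_genomic()
  eff <- backsolve_marker_effects(fg, pan$geno, pan$grm)
  sel1 <- select_qtl(eff, pan$map, n_select = 5)
  perm <- sample(nrow(eff))
  sel2 <- select_qtl(eff[perm, ], pan$map, n_select = 5)
  expect_setequal(sel1$marker, sel2$marker)
  # on-chromosome spacing respects the window
  by_chrom <- split(sel1$pos, sel1$chrom)
  for (p in by_chrom) if (length(p) > 1) expect_gt(min(diff(sort(p))), 25)
})

test_that("a marker-determined trait is recovered exactly by the QTL model", {
  pan <- small_panel()
  trial <- pan$trial
  qcol <- pan$geno[, 17]
  trial$yq <- 2 + 1.7 * qcol[trial$line_id]
  qfit <- fit_qtl(trial, "yq", colnames(pan$geno)[17], pan$geno,
                  use_blocks = FALSE, spatial = FALSE)
  expect_equal(unname(qfit$qtl_effects$beta), 1.7, tolerance = 1e-6)
  expect_lt(qfit$components$sigma2_p, 1e-4)
})

test_that("an empty selection collapses the QTL model onto the baseline", {
  pan <- small_panel()
  fb <- small_fit_baseline()
  q0 <- fit_qtl(pan$trial, "y", character(), pan$geno)
  expect_equal(q0$logL, fb$logL, tolerance = 1e-5)
})

test_that("cross-validation partitions lines once and evenly", {
  pan <- small_panel()
  cv <- suppressMessages(cross_validate(
    pan$trial, "y", pan$geno, pan$map, grm = pan$grm,
    methods = "genomic", k = 5, seed = 42))
  sizes <- table(cv$folds$fold)
  expect_equal(length(sizes), 5L)
  expect_lte(diff(range(sizes)), 1)
  per_line <- table(cv$predictions$line_id[cv$predictions$method == "genomic"])
  expect_true(all(per_line == 1))
  expect_setequal(names(per_line), unique(pan$trial$line_id))

  # same seed, same folds
  cv2 <- suppressMessages(cross_validate(
    pan$trial, "y", pan$geno, pan$map, grm = pan$grm,
    methods = "genomic", k = 5, seed = 42))
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$accuracy, cv2$accuracy)

  # accuracies live in a sensible range for a heritable additive trait
  expect_gt(cv$accuracy$accuracy_additive, 0.5)
  td <- tidy(cv)
  expect_true(all(c("accuracy_additive", "accuracy_total",
                    "additive_proportion") %in% names(td)))
})

test_that("accuracy-additivity correlations behave on known inputs", {
  df <- tibble::tibble(accuracy_additive = c(0.9, 0.8, 0.7),
                       accuracy_total = c(0.6, 0.5, 0.4),
                       additive_proportion = c(90, 80, 70))
  out <- accuracy_vs_additivity(df)
  expect_equal(out$r, c(1, 1))
  dfc <- df; dfc$accuracy_total <- 0.5
  expect_true(is.na(suppressMessages(
    accuracy_vs_additivity(dfc))$r[1]))
  expect_error(accuracy_vs_additivity(df[1:2, ]),
               class = "fieldblup_input_error")
})
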