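# Consensus-map scaling, map summaries, LD decay.

test_that("linkage-group scaling recovers exact rescalings", {
  cons <- c(a = 0, b = 30, c = 75, d = 120)
  ident <- list(data.frame(marker = names(cons), pos = unname(cons)))
  res <- scale_linkage_group(cons, ident, weights = 100)
  expect_equal(res$R, 1, tolerance = res$grid_step)
  expect_equal(res$R_wls, 1, tolerance = 1e-12)

  halved <- list(data.frame(marker = names(cons), pos = unname(cons) / 2))
  res2 <- scale_linkage_group(cons, halved, weights = 100)
  expect_equal(res2$R, 0.5, tolerance = res2$grid_step)
  expect_equal(res2$R_wls, 0.5, tolerance = 1e-12)
})

test_that("profiled scale factor matches the closed-form WLS minimiser", {
  set.seed(14)
  base <- sort(runif(40, 0, 150))
  names(base) <- sprintf("m%02d", seq_along(base))
  comps <- list(
    data.frame(marker = names(base), pos = unname(base) * 0.8),
    data.frame(marker = names(base)[1:25], pos = unname(base[1:25]) * 1.2))
  res <- scale_linkage_group(base, comps, weights = c(100, 50))
  expect_lt(abs(res$R - res$R_wls), res$grid_step)
  expect_gt(res$R, 0)

  # degenerate inputs
  expect_error(scale_linkage_group(c(a = 5, b = 5), comps, weights = 1),
               class = "fieldblup_degenerate_group_error")
  stranger <- list(data.frame(marker = c("x", "y"), pos = c(0, 10)))
  expect_error(scale_linkage_group(base, stranger, weights = 1),
               class = "fieldblup_cannot_scale_error")
})

test_that("scale_map rescales groups independently and is a fixed point", {
  map <- tibble::tibble(marker = sprintf("m%02d", 1:20),
                        chrom = rep(c("1A", "2A"), each = 10),
                        pos = rep(seq(0, 90, by = 10), 2))
  comps <- list(
    `1A` = list(data.frame(marker = sprintf("m%02d", 1:10),
                           pos = seq(0, 45, by = 5))),
    `2A` = list(data.frame(marker = sprintf("m%02d", 11:20),
                           pos = seq(0, 90, by = 10))))
  scaled <- scale_map(map, comps, weights = 100)
  sc <- attr(scaled, "scaling")
  expect_equal(sc$R[sc$chrom == "2A"], 1, tolerance = 2e-3)
  expect_equal(sc$R[sc$chrom == "1A"], 0.5, tolerance = 1e-3)
  expect_equal(scaled$pos[scaled$chrom == "2A"],
               map$pos[map$chrom == "2A"], tolerance = 1e-3)
  expect_equal(max(scaled$pos[scaled$chrom == "1A"]), 45, tolerance = 0.2)
  expect_identical(scaled$marker, map$marker)

  # re-profiling the scaled group against the same components gives R ~ 1
  re <- scale_linkage_group(
    stats::setNames(scaled$pos[scaled$chrom == "1A"], map$marker[1:10]),
    comps$`1A`, weights = 100)
  expect_lt(abs(re$R - 1), re$grid_step + 1e-3)
})

test_that("map summaries apply the count identities", {
  map <- tibble::tibble(marker = sprintf("m%02d", 1:10), chrom = "1A",
                        pos = rep(seq(0, 20, by = 5), each = 2))
  s <- summarize_map(map, grouping = "chromosome")
  expect_equal(s$markers_per_position, 2)
  expect_equal(s$mean_interval_cM, 5)
  expect_equal(s$length_cM, 20)

  one <- tibble::tibble(marker = c("a", "b"), chrom = "1A", pos = c(3, 3))
  s1 <- summarize_map(one, grouping = "chromosome")
  expect_equal(s1$length_cM, 0)
  expect_true(is.na(s1$mean_interval_cM))
})

test_that("aggregate map summaries pool lengths and interval counts", {
  set.seed(30)
  map <- tibble::tibble(
    marker = sprintf("m%03d", 1:120),
    chrom = rep(paste0(rep(1:2, each = 2), c("A", "B")), each = 30),
    pos = as.vector(replicate(4, sort(runif(30, 0, 100)))))
  s <- summarize_map(map)
  per <- s[s$group == "chromosome", ]
  tot <- s[s$group == "total", ]
  expect_equal(tot$n_markers, sum(per$n_markers))
  expect_equal(tot$length_cM, sum(per$length_cM))
  expect_equal(tot$mean_interval_cM,
               sum(per$length_cM) / sum(per$n_positions - 1))
  gen <- s[s$group == "genome", ]
  expect_equal(sort(gen$level), c("A", "B"))
  expect_equal(sum(gen$n_markers), 120)
})

test_that("r2 equals squared Pearson correlation with hand-checked cases", {
  lines <- paste0("l", 1:4)
  M <- cbind(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1), z = c(0, 1, 1, 1),
             x2 = c(0, 0, 1, 1))
  rownames(M) <- lines
  map <- tibble::tibble(marker = c("x", "y", "z", "x2"), chrom = "1A",
                        pos = c(0, 5, 10, 15))
  pairs <- ld_r2(M, map, min_complete = 1L)
  get <- function(a, b) pairs$r2[(pairs$marker1 == a & pairs$marker2 == b) |
                                   (pairs$marker1 == b & pairs$marker2 == a)]
  expect_equal(get("x", "x2"), 1)
  expect_equal(get("x", "y"), 0)
  expect_equal(get("x", "z"), 1 / 3)

  # allele-code flip invariance
  Mf <- M; Mf[] <- -Mf
  pf <- ld_r2(Mf, map, min_complete = 1L)
  expect_equal(pf$r2, pairs$r2)

  # separations and intra-chromosome restriction
  expect_true(all(pairs$sep_cM >= 0))
  map2 <- map; map2$chrom <- c("1A", "1A", "2B", "2B")
  p2 <- ld_r2(M, map2, min_complete = 1L)
  expect_equal(nrow(p2), 2)
})

test_that("LD decays with map distance in a linked panel", {
  pan <- ld_panel()
  suppressMessages(pairs <- ld_r2(pan$geno, pan$map, max_separation = 60))
  bins <- ld_decay_bins(pairs, bin_edges = c(0, 4, 8, 12, 20, 40, 60))
  med <- bins$median[bins$n > 0]
  expect_true(all(diff(med[1:3]) <= 0))
  expect_true(all(bins$median <= bins$q3 & bins$q1 <= bins$median,
                  na.rm = TRUE))

  # single pair and empty-bin contracts
  single <- pairs[1, ]
  b1 <- ld_decay_bins(single, bin_edges = c(0, 100, 200))
  expect_equal(b1$median[b1$n > 0], single$r2)
  expect_true(any(b1$n == 0))
})
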