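# Marker-effect back-solving, outlier statistics, prediction of new lines.

#' Extract line BLUPs from a fitted model
#'
#' @param fit A `panel_fit`.
#' @return Tibble with `line_id` and `g_t` (baseline) or `g_a`, `g_p`
#'   (genomic) or `g_p`, `g_qtl` (QTL model).
#' @export
extract_blups <- function(fit) {
  stopifnot(inherits(fit, "panel_fit"))
  fit$blup
}

# Z_g' P Z_g in the line basis, from the stored MME solves. P is applied
# implicitly: H0^-1 Zg = Ri Zg - Ri W S^-1 W' Ri Zg, then the fixed-effect
# projection is removed and the result scaled by the profiled sigma2.
zg_p_zg <- function(fit) {
  sv <- fit$solver
  dat <- sv$dat
  det <- sv$det
  # rotated genetic block indices within W = [Zb, ZgU]
  iwg <- if (dat$b > 0L) dat$b + seq_len(dat$m) else seq_len(dat$m)
  GRW <- det$BigG[det$ig, det$iw, drop = FALSE]      # ZgU' Ri W
  GRG <- det$BigG[det$ig, det$ig, drop = FALSE]
  XRG <- det$BigG[det$ix, det$ig, drop = FALSE]
  sol <- backsolve(det$cholS, backsolve(det$cholS, t(GRW), transpose = TRUE))
  GH0G <- GRG - GRW %*% sol
  WRX <- det$BigG[det$iw, det$ix, drop = FALSE]
  XH0G <- XRG - crossprod(backsolve(det$cholS,
                                    backsolve(det$cholS, WRX, transpose = TRUE)),
                          t(GRW))
  XH0Xinv_XH0G <- backsolve(det$cholXHX,
                            backsolve(det$cholXHX, XH0G, transpose = TRUE))
  Trot <- (GH0G - crossprod(XH0G, XH0Xinv_XH0G)) / det$s2
  if (is.null(dat$U)) as.matrix(Trot) else dat$U %*% Trot %*% t(dat$U)
}

#' Back-solve SNP marker effects from a genomic fit
#'
#' Converts the additive genetic values of a fitted genomic model into
#' per-marker effects `g_m = M' G_s^-1 g_a` (computed via solves against
#' `G_s`, never an explicit inverse), with prediction variances from the
#' diagonal of `M' G_s^-1 var(g_a) G_s^-1 M` and the per-marker outlier
#' statistic `t = g_m^2 / var(g_m)`. The identity `M g_m = r g_a` (with
#' `r` the GRM trace scaling) holds by construction and is a useful
#' numerical check on any fit.
#'
#' @param fit A genomic `panel_fit`.
#' @param M The lines x markers genotype matrix the GRM was built from.
#' @param grm The matching [build_grm()] object.
#' @return A `marker_effects` tibble: `marker`, `effect`, `var`, `t`,
#'   `flagged` (zero or clipped variance), with attributes `r` and
#'   `trait`.
#' @export
backsolve_marker_effects <- function(fit, M, grm) {
  stopifnot(inherits(fit, "panel_fit"), inherits(grm, "grm"))
  if (fit$kind != "genomic") {
    abort("marker effects are back-solved from a genomic fit.",
          class = "fieldblup_input_error")
  }
  if (!isTRUE(all.equal(grm$marker_fingerprint, fingerprint_markers(M)))) {
    abort("GRM was not built from this genotype matrix (fingerprint mismatch).",
          class = "fieldblup_input_error")
  }
  lines <- fit$blup$line_id
  Msub <- M[lines, , drop = FALSE]
  # g_m = sigma2_a M' Zg' P y; equivalently M' G_s^-1 g_a, but the stored
  # v = Zg' P y avoids touching G_s^-1 explicitly
  v <- fit$solver$v
  gm <- as.vector(crossprod(Msub, fit$components$sigma2_a * v))

  Tm <- zg_p_zg(fit)
  TM <- Tm %*% Msub
  vm <- unname(fit$components$sigma2_a^2 * colSums(Msub * TM))
  flagged <- vm <= 1e-12 * max(vm, 0)
  clipped <- vm < 0
  vm[clipped] <- 1e-12 * max(abs(vm), 1e-300)
  t_stat <- ifelse(flagged, 0, gm^2 / vm)
  out <- tibble(marker = colnames(M), effect = gm, var = vm, t = t_stat,
                flagged = flagged | clipped)
  class(out) <- c("marker_effects", class(out))
  attr(out, "r") <- grm$r
  attr(out, "trait") <- fit$trait
  attr(out, "marker_fingerprint") <- grm$marker_fingerprint
  out
}

#' Outlier statistics from a marker-effect set
#'
#' Elementwise `t = effect^2 / var`; markers with numerically zero
#' variance get `t = 0` and a flag.
#'
#' @param effects A `marker_effects` tibble (or any tibble with `effect`
#'   and `var` columns).
#' @return The input with the `t` and `flagged` columns (re)computed.
#' @export
outlier_statistics <- function(effects) {
  if (!all(c("effect", "var") %in% names(effects))) {
    abort("`effects` needs columns effect and var.",
          class = "fieldblup_input_error")
  }
  vm <- effects$var
  neg <- vm < 0
  if (any(neg)) {
    warn(sprintf("%d negative marker-effect variances clipped to floor.",
                 sum(neg)))
    vm[neg] <- 1e-12 * max(abs(vm), 1e-300)
  }
  zero <- vm <= 1e-12 * max(vm, 0)
  effects$t <- ifelse(zero, 0, effects$effect^2 / vm)
  effects$flagged <- zero | neg
  effects
}

#' Genomic prediction of new lines from back-solved marker effects
#'
#' `g_hat = M_new g_m`: a pure matrix-vector product, no refitting. The
#' new lines must be genotyped at the identical marker set and order used
#' in training.
#'
#' @param M_new New-lines x markers genotype matrix.
#' @param effects A `marker_effects` tibble.
#' @return Tibble: `line_id`, `g_hat`.
#' @export
predict_new <- function(M_new, effects) {
  if (!identical(colnames(M_new), effects$marker)) {
    missing_m <- setdiff(effects$marker, colnames(M_new))
    abort(paste0("marker set/order mismatch with training matrix",
                 if (length(missing_m)) paste0("; missing: ",
                   paste(head(missing_m, 5L), collapse = ", "),
                   if (length(missing_m) > 5L) ", ...")),
          class = "fieldblup_input_error")
  }
  tibble(line_id = rownames(M_new),
         g_hat = as.vector(M_new %*% effects$effect))
}

#' Genome scan plot of marker outlier statistics
#'
#' @param effects A `marker_effects` tibble.
#' @param map Map tibble for genome positions.
#' @return A ggplot object.
#' @export
plot_outlier_scan <- function(effects, map) {
  df <- effects %>%
    left_join(map, by = "marker") %>%
    filter(!is.na(.data$chrom))
  ggplot(df, aes(x = .data$pos, y = .data$t)) +
    geom_point(size = 0.6, alpha = 0.7, colour = "grey30") +
    facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "position (cM)", y = "marker outlier statistic t") +
    theme_minimal()
}
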