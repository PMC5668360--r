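#' Scale one consensus linkage group against its component maps
#'
#' Consensus maps merged from several bi-parental linkage maps are known to
#' inflate linkage-group lengths. The scale factor for group *j* minimises
#' the population-size-weighted squared deviation between scaled consensus
#' positions `C R_j` and the component-map positions `M_i` of shared
#' markers. The minimiser is located by profiling the target group length
#' over a grid: `R_j = D_bar / D_c` with `D_bar` running over a window of
#' +/-20% around the weighted mean component group length (1001 points).
#' The closed-form weighted-least-squares minimiser
#' `R* = sum(w C M) / sum(w C^2)` is returned alongside as an internal
#' cross-check.
#'
#' @param consensus Named numeric vector of consensus positions (cM) for the
#'   group's markers; names are marker ids.
#' @param components List of data frames with columns `marker`, `pos`, one
#'   per bi-parental map (only markers shared with the consensus group are
#'   used).
#' @param weights Numeric vector of component weights, typically the mapping
#'   population sizes; recycled if length 1.
#' @param window Half-width of the profiling window as a fraction of the
#'   mean component length.
#' @param n_grid Number of grid points profiled.
#' @return An `lg_scaling` list: `R` (profiled factor), `R_wls` (closed
#'   form), `consensus_length`, `target_length`, `objective`, `n_shared`.
#' @export
#' @examples
#' cons <- c(a = 0, b = 60, c = 120)
#' comp <- list(data.frame(marker = c("a", "b", "c"), pos = c(0, 30, 60)))
#' scale_linkage_group(cons, comp, weights = 100)$R
scale_linkage_group <- function(consensus, components, weights,
                                window = 0.2, n_grid = 1001L) {
  if (is.null(names(consensus)) || !length(consensus)) {
    abort("`consensus` must be a named vector of positions.",
          class = "fieldblup_input_error")
  }
  Dc <- diff(range(consensus))
  if (Dc <= 0) {
    abort("degenerate linkage group: consensus length is zero.",
          class = "fieldblup_degenerate_group_error")
  }
  weights <- rep_len(as.numeric(weights), length(components))
  if (any(weights <= 0)) {
    abort("component weights must be positive.", class = "fieldblup_input_error")
  }
  shared <- purrr::map2(components, weights, function(cm, w) {
    idx <- match(names(consensus), cm$marker)
    keep <- !is.na(idx)
    if (!any(keep)) return(NULL)
    tibble(C = unname(consensus[keep]), M = cm$pos[idx[keep]], w = w,
           len = diff(range(cm$pos[idx[keep]])))
  })
  shared <- purrr::compact(shared)
  if (!length(shared)) {
    abort("no markers shared between the consensus group and any component map.",
          class = "fieldblup_cannot_scale_error")
  }
  tab <- bind_rows(shared)
  comp_len <- vapply(shared, function(s) s$len[1L], 0)
  comp_w <- vapply(shared, function(s) s$w[1L], 0)
  mean_len <- sum(comp_w * comp_len) / sum(comp_w)
  if (mean_len <= 0) mean_len <- Dc  # single-position components; fall back

  grid_len <- seq((1 - window) * mean_len, (1 + window) * mean_len,
                  length.out = n_grid)
  grid_R <- grid_len / Dc
  swc2 <- sum(tab$w * tab$C^2)
  swcm <- sum(tab$w * tab$C * tab$M)
  swm2 <- sum(tab$w * tab$M^2)
  obj <- swc2 * grid_R^2 - 2 * swcm * grid_R + swm2
  best <- which.min(obj)
  structure(list(R = grid_R[best],
                 R_wls = swcm / swc2,
                 consensus_length = Dc,
                 target_length = grid_len[best],
                 objective = obj[best],
                 grid_step = diff(grid_R[1:2]),
                 n_shared = nrow(tab)),
            class = "lg_scaling")
}

#' Scale all linkage groups of a consensus map
#'
#' Applies [scale_linkage_group()] per chromosome and multiplies positions
#' by the group's profiled scale factor; marker order is preserved. Groups
#' that cannot be scaled (no shared markers, or degenerate length) keep
#' `R = 1` with a warning.
#'
#' @param map Consensus map tibble (`marker`, `chrom`, `pos`).
#' @param components Named list (by chromosome) of lists of component data
#'   frames as in [scale_linkage_group()]; alternatively a flat list applied
#'   to every chromosome by marker matching.
#' @param weights Component weights (population sizes), recycled per group.
#' @param ... Passed to [scale_linkage_group()].
#' @return The map with scaled `pos`; attribute `scaling` is a tibble of
#'   per-group factors.
#' @export
scale_map <- function(map, components, weights, ...) {
  validate_map(map)
  chroms <- unique(map$chrom)
  by_chrom <- !is.null(names(components)) && all(chroms %in% names(components))
  out <- map
  scal <- purrr::map_dfr(chroms, function(ch) {
    rows <- map$chrom == ch
    cons <- setNames(map$pos[rows], map$marker[rows])
    comp <- if (by_chrom) components[[ch]] else components
    res <- tryCatch(scale_linkage_group(cons, comp, weights, ...),
                    error = function(e) {
                      warn(sprintf("linkage group %s not scaled (%s); keeping R = 1.",
                                   ch, conditionMessage(e)))
                      NULL
                    })
    R <- if (is.null(res)) 1 else res$R
    out$pos[rows] <<- map$pos[rows] * R
    tibble(chrom = ch, R = R,
           consensus_length = diff(range(map$pos[rows])),
           scaled_length = diff(range(map$pos[rows])) * R)
  })
  attr(out, "scaling") <- scal
  out
}
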