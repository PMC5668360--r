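#' Simulate a genetic map
#'
#' Places markers along each chromosome either on an even grid spanning
#' `[0, chrom_length]` or on an evenly spaced grid with Gaussian jitter
#' (clamped to the chromosome and sorted). With 21 chromosomes the wheat
#' naming convention 1A..7D is used; otherwise chromosomes are labelled
#' C1, C2, ...
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `marker`, `chrom`, `pos` (cM).
#' @export
#' @examples
#' sim_map(sim_config(n_lines = 10, n_chromosomes = 2, markers_per_chrom = 5,
#'                    trial_ranges = 4, seed = 1))
sim_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_chromosomes
  m <- config$markers_per_chrom
  L <- config$chrom_length
  chroms <- if (k == 21L) {
    paste0(rep(1:7, each = 3L), rep(c("A", "B", "D"), 7L))
  } else {
    paste0("C", seq_len(k))
  }
  with_seed(config$seed, {
    purrr::map_dfr(seq_len(k), function(i) {
      pos <- seq(0, L, length.out = m)
      if (config$placement == "jitter") {
        pos <- pos + rnorm(m, sd = L / (4 * m))
        pos <- sort(pmin(pmax(pos, 0), L))
      }
      tibble(marker = sprintf("%s_M%04d", chroms[i], seq_len(m)),
             chrom = chroms[i], pos = pos)
    })
  })
}
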