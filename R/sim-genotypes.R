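# One Haldane meiosis: crossover count Poisson in the map length (Morgans),
# crossover positions uniform, random starting phase, no interference.
meiosis_gamete <- function(h1, h2, pos, L) {
  nxo <- rpois(1L, L / 100)
  if (nxo == 0L) return(if (runif(1) < 0.5) h1 else h2)
  seg <- findInterval(pos, sort(runif(nxo, 0, L)))
  phase <- (seg + sample.int(2L, 1L)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate panel genotypes by founder crossing, meiosis and selfing
#'
#' Founder inbreds receive allele draws per marker (allele frequencies
#' uniform on 0.05-0.95). Each panel line descends from an F1 between two
#' random founders followed by `selfing_generations` rounds of selfing.
#' Meiosis uses the Haldane (no-interference) model: crossover counts are
#' Poisson with mean equal to the chromosome length in Morgans and crossover
#' positions are uniform, so map distance drives recombination and hence the
#' linkage disequilibrium structure of the panel. Allele codes are
#' homozygote -1/+1 with residual heterozygotes 0 (or 0/1 with 0.5 under the
#' `"01"` coding).
#'
#' @param map Genetic map tibble from [sim_map()].
#' @param config A [sim_config()]; its chromosome set must match the map.
#' @return Numeric lines x markers matrix with line ids as rownames, marker
#'   names as colnames and attributes `coding` and `map_fingerprint`.
#' @export
sim_genotypes <- function(map, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_map(map)
  chroms <- unique(map$chrom)
  if (length(chroms) != config$n_chromosomes) {
    abort("map chromosomes do not match `config$n_chromosomes`.",
          class = "fieldblup_structure_error")
  }
  n <- config$n_lines
  g <- config$selfing_generations
  line_ids <- sprintf("L%05d", seq_len(n))

  with_seed(config$seed + 1L, {
    parents <- replicate(n, sample.int(config$n_founders, 2L, replace = FALSE))
    geno <- lapply(chroms, function(ch) {
      pos <- map$pos[map$chrom == ch]
      m <- length(pos)
      L <- max(config$chrom_length, max(pos))
      freq <- runif(m, 0.05, 0.95)
      founders <- matrix(rbinom(config$n_founders * m, 1L, rep(freq, each = config$n_founders)) * 2L - 1L,
                         nrow = config$n_founders)
      out <- matrix(0, nrow = n, ncol = m)
      for (i in seq_len(n)) {
        h1 <- founders[parents[1L, i], ]
        h2 <- founders[parents[2L, i], ]
        if (g > 0L) for (s in seq_len(g)) {
          if (identical(h1, h2)) break  # fully inbred, meiosis is a no-op
          n1 <- meiosis_gamete(h1, h2, pos, L)
          h2 <- meiosis_gamete(h1, h2, pos, L)
          h1 <- n1
        }
        out[i, ] <- (h1 + h2) / 2
      }
      out
    })
    M <- do.call(cbind, geno)
    dimnames(M) <- list(line_ids, map$marker)
    if (config$allele_coding == "01") M <- (M + 1) / 2
    attr(M, "coding") <- config$allele_coding
    attr(M, "map_fingerprint") <- sum(map$pos) + length(chroms)
    M
  })
}

#' Mask genotype calls at random
#'
#' Sets entries missing uniformly at random at the given rate and records
#' the mask so imputation accuracy is measurable against the truth.
#'
#' @param M Lines x markers genotype matrix.
#' @param missing_rate Fraction of entries to mask, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return `M` with `NA`s inserted; attribute `mask` holds the masked index
#'   matrix (`which(..., arr.ind = TRUE)` layout).
#' @export
mask_genotypes <- function(M, missing_rate, seed = NULL) {
  validate_marker_matrix(M)
  check_fraction(missing_rate, "missing_rate", lo = 0, hi = 1, open_hi = TRUE)
  if (missing_rate == 0) {
    attr(M, "mask") <- matrix(integer(), 0L, 2L,
                              dimnames = list(NULL, c("row", "col")))
    return(M)
  }
  with_seed(seed, {
    hit <- which(runif(length(M)) < missing_rate)
    mask <- arrayInd(hit, dim(M))
    colnames(mask) <- c("row", "col")
    M[hit] <- NA_real_
    attr(M, "mask") <- mask
    M
  })
}
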