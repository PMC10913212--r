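#' Simulate Hi-C contact pairs with power-law distance decay
#'
#' Cis pairs dominate chromatin-contact data: their genomic separation `s` is
#' drawn with density proportional to `s^(-decay_exponent)` between
#' `min_separation` and the chromosome length, reproducing the diagonal
#' pattern of real contact maps. A fraction of pairs is trans
#' (inter-chromosomal, positions uniform). Chromosomes are chosen
#' proportionally to length. Pairs are reported in the coordinates of the
#' genome they were simulated on.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n_pairs Number of pairs (> 0).
#' @param decay_exponent Positive decay exponent of the cis contact density.
#' @param trans_fraction Fraction in [0, 1) of trans pairs.
#' @param min_separation Minimum cis separation in bp.
#' @param seed Integer RNG seed.
#' @return Data frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
simulate_hic_pairs <- function(genome, n_pairs, decay_exponent = 1,
                               trans_fraction = 0.05,
                               min_separation = 1000, seed = 1L) {
  if (n_pairs <= 0) stop("n_pairs must be positive")
  if (decay_exponent <= 0) stop("decay_exponent must be positive")
  if (trans_fraction < 0 || trans_fraction >= 1)
    stop("trans_fraction must be in [0, 1)")
  lens <- nchar(genome)
  if (min_separation >= min(lens)) stop("min_separation too large")

  # inverse-CDF sampler for density ~ s^(-a) on [s0, smax]
  rdecay <- function(n, a, s0, smax) {
    u <- runif(n)
    if (abs(a - 1) < 1e-9) {
      s0 * (smax / s0)^u
    } else {
      (s0^(1 - a) + u * (smax^(1 - a) - s0^(1 - a)))^(1 / (1 - a))
    }
  }

  with_seed_or_not(seed, {
    is_trans <- runif(n_pairs) < trans_fraction
    n_cis <- sum(!is_trans); n_trans <- sum(is_trans)

    cis <- NULL
    if (n_cis > 0L) {
      chrom <- sample(names(genome), n_cis, replace = TRUE, prob = lens)
      L <- lens[chrom]
      # locus-pair density ~ s^(-a) means the separation marginal carries the
      # pair-multiplicity factor (L - s): sample by rejection
      s <- pmin(round(rdecay(n_cis, decay_exponent, min_separation,
                             as.numeric(L))), L - 1L)
      reject <- runif(n_cis) > (L - s) / L
      while (any(reject)) {
        k <- sum(reject)
        s[reject] <- pmin(round(rdecay(k, decay_exponent, min_separation,
                                       as.numeric(L[reject]))),
                          L[reject] - 1L)
        reject[reject] <- runif(k) > (L[reject] - s[reject]) / L[reject]
      }
      p1 <- floor(runif(n_cis) * (L - s)) + 1L
      swap <- runif(n_cis) < 0.5
      a <- ifelse(swap, p1 + s, p1); b <- ifelse(swap, p1, p1 + s)
      cis <- data.frame(chrom1 = chrom, pos1 = as.integer(a),
                        chrom2 = chrom, pos2 = as.integer(b),
                        stringsAsFactors = FALSE)
    }
    trans <- NULL
    if (n_trans > 0L) {
      if (length(genome) < 2L) stop("trans pairs require >= 2 chromosomes")
      c1 <- sample(names(genome), n_trans, replace = TRUE, prob = lens)
      c2 <- vapply(c1, function(cc) {
        others <- setdiff(names(genome), cc)
        sample(others, 1L, prob = lens[others])
      }, character(1), USE.NAMES = FALSE)
      trans <- data.frame(
        chrom1 = c1, pos1 = floor(runif(n_trans) * lens[c1]) + 1L,
        chrom2 = c2, pos2 = floor(runif(n_trans) * lens[c2]) + 1L,
        stringsAsFactors = FALSE)
    }
    out <- rbind(cis, trans)
    rownames(out) <- NULL
    out
  })
}
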