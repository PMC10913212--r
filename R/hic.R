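#' Bin Hi-C contact pairs into per-chromosome matrices
#'
#' A pair (p1, p2) on one chromosome increments bin (i, j) and its
#' transpose, so cis matrices are symmetric and their total equals twice
#' the number of binned cis pairs. Trans pairs are binned into one
#' rectangular matrix per unordered chromosome pair. Pairs with coordinates
#' outside the stated chromosome lengths are dropped and counted.
#'
#' @param pairs Data frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @param bin_size Bin size in bp (> 0; default 100 kb).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A `contact_matrices` object: list with `cis` (named list of
#'   symmetric matrices), `trans` (named list, names `"A|B"`), `bin_size`,
#'   `chrom_lengths`, `n_used`, `n_dropped`.
#' @export
bin_contacts <- function(pairs, bin_size = 100000L, chrom_lengths) {
  if (bin_size <= 0) stop("bin_size must be positive")
  known <- pairs$chrom1 %in% names(chrom_lengths) &
    pairs$chrom2 %in% names(chrom_lengths)
  inb <- known & pairs$pos1 >= 1 & pairs$pos2 >= 1 &
    pairs$pos1 <= chrom_lengths[pairs$chrom1] &
    pairs$pos2 <= chrom_lengths[pairs$chrom2]
  dropped <- sum(!inb)
  p <- pairs[inb, , drop = FALSE]

  nbins <- ceiling(chrom_lengths / bin_size)
  cis <- lapply(names(chrom_lengths), function(chrom) {
    n <- nbins[[chrom]]
    m <- matrix(0L, n, n)
    sel <- p$chrom1 == chrom & p$chrom2 == chrom
    if (any(sel)) {
      i <- (p$pos1[sel] - 1L) %/% bin_size + 1L
      j <- (p$pos2[sel] - 1L) %/% bin_size + 1L
      for (idx in seq_along(i)) {
        m[i[idx], j[idx]] <- m[i[idx], j[idx]] + 1L
        m[j[idx], i[idx]] <- m[j[idx], i[idx]] + 1L
      }
    }
    m
  })
  names(cis) <- names(chrom_lengths)

  trans <- list()
  tsel <- p$chrom1 != p$chrom2
  if (any(tsel)) {
    tp <- p[tsel, , drop = FALSE]
    flip <- tp$chrom1 > tp$chrom2
    tmp <- tp[flip, ]
    tp[flip, c("chrom1", "pos1", "chrom2", "pos2")] <-
      tmp[, c("chrom2", "pos2", "chrom1", "pos1")]
    key <- paste0(tp$chrom1, "|", tp$chrom2)
    for (kk in unique(key)) {
      cc <- strsplit(kk, "|", fixed = TRUE)[[1]]
      m <- matrix(0L, nbins[[cc[1]]], nbins[[cc[2]]])
      sub <- tp[key == kk, ]
      i <- (sub$pos1 - 1L) %/% bin_size + 1L
      j <- (sub$pos2 - 1L) %/% bin_size + 1L
      for (idx in seq_along(i)) m[i[idx], j[idx]] <- m[i[idx], j[idx]] + 1L
      trans[[kk]] <- m
    }
  }
  structure(list(cis = cis, trans = trans, bin_size = bin_size,
                 chrom_lengths = chrom_lengths,
                 n_used = nrow(p), n_dropped = dropped),
            class = "contact_matrices")
}

#' Expected contact count per bin distance
#'
#' Averages a cis contact matrix over all bin pairs at each off-diagonal
#' distance, yielding the empirical distance-decay curve used as the
#' expectation in junction scoring.
#'
#' @param matrix Symmetric cis contact matrix with at least 10 bins.
#' @return Numeric vector `decay` where `decay[d + 1]` is the mean count at
#'   bin distance `d`.
#' @export
expected_decay <- function(matrix) {
  n <- nrow(matrix)
  if (n < 10L) stop("cis matrix must have at least 10 bins")
  vapply(0:(n - 1L), function(d) {
    idx <- seq_len(n - d)
    mean(matrix[cbind(idx, idx + d)])
  }, numeric(1))
}

#' Score the Hi-C support of a candidate junction
#'
#' Compares the observed number of contacts spanning `position` (one end
#' within `flank` bp left of it, the other within `flank` bp right) with
#' the count expected from the chromosome-wide distance decay over the same
#' bin pairs. A real join shows the usual diagonal signal (ratio near 1);
#' a junction absent from the sampled genome leaves an empty anti-diagonal
#' block (ratio near 0).
#'
#' @param matrix Symmetric cis contact matrix.
#' @param position Candidate junction position in bp.
#' @param flank Flank size in bp (default 500 kb; must cover >= 2 bins).
#' @param bin_size Bin size of `matrix` in bp.
#' @param gap_below Ratio below which the verdict is `"gap"` (default 0.2).
#' @param supported_above Ratio at or above which the verdict is
#'   `"supported"` (default 0.5).
#' @return A `junction_score`: list with `position`, `observed`, `expected`,
#'   `ratio` and `verdict` (`"supported"`, `"gap"`, `"ambiguous"`, or
#'   `"undetermined"` when the expectation is zero).
#' @export
junction_score <- function(matrix, position, flank = 500000L,
                           bin_size = 100000L,
                           gap_below = 0.2, supported_above = 0.5) {
  n <- nrow(matrix)
  L <- n * bin_size
  if (position <= 0 || position > L) stop("position outside chromosome")
  if (flank < 2L * bin_size) stop("flank must cover at least 2 bins")
  bin_of <- function(p) (as.integer(p) - 1L) %/% bin_size + 1L
  left <- max(1L, bin_of(position - flank + 1L)):bin_of(position)
  right_lo <- bin_of(position) + 1L
  right <- if (right_lo > n) integer(0) else
    right_lo:min(n, bin_of(position + flank))
  if (length(left) == 0L || length(right) == 0L)
    stop("flank does not cover bins on both sides of the position")

  decay <- expected_decay(matrix)
  obs <- sum(matrix[left, right, drop = FALSE])
  d <- abs(outer(left, right, "-"))
  expd <- sum(decay[d + 1L])
  ratio <- if (expd > 0) obs / expd else NA_real_
  verdict <- if (expd == 0) "undetermined"
  else if (ratio < gap_below) "gap"
  else if (ratio >= supported_above) "supported"
  else "ambiguous"
  structure(list(position = position, observed = obs, expected = expd,
                 ratio = ratio, verdict = verdict),
            class = "junction_score")
}

#' Swap distal chromosome segments to simulate a translocation
#'
#' Exchanges the sequence distal to `breakpoint_a` on `chrom_a` with the
#' sequence distal to `breakpoint_b` on `chrom_b`. Applied to a pair of
#' hybrid HE chromosomes at their breakpoints, this reconstitutes the
#' unexchanged parental chromosomes - the negative control of the Hi-C
#' junction check. Applying the same swap twice restores the input; total
#' genome length is conserved.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom_a,chrom_b Distinct chromosome names.
#' @param breakpoint_a,breakpoint_b Last bp of the proximal segment kept on
#'   each chromosome.
#' @return The modified genome.
#' @export
simulate_translocation_reference <- function(genome, chrom_a, chrom_b,
                                             breakpoint_a, breakpoint_b) {
  if (chrom_a == chrom_b) stop("chrom_a and chrom_b must differ")
  la <- nchar(genome[[chrom_a]]); lb <- nchar(genome[[chrom_b]])
  if (breakpoint_a < 1 || breakpoint_a >= la ||
      breakpoint_b < 1 || breakpoint_b >= lb)
    stop("breakpoints must lie within the chromosomes")
  a <- genome[[chrom_a]]; b <- genome[[chrom_b]]
  genome[[chrom_a]] <- paste0(substr(a, 1L, breakpoint_a),
                              substr(b, breakpoint_b + 1L, lb))
  genome[[chrom_b]] <- paste0(substr(b, 1L, breakpoint_b),
                              substr(a, breakpoint_a + 1L, la))
  genome
}

#' Express contact pairs in the coordinates of a translocated reference
#'
#' Stands in for re-mapping reads onto a modified reference: positions
#' distal to the breakpoints swap chromosome (exact liftover, valid because
#' simulated pairs are exact coordinates).
#'
#' @param pairs Data frame `chrom1`, `pos1`, `chrom2`, `pos2` in the
#'   original coordinates.
#' @inheritParams simulate_translocation_reference
#' @return The pairs in modified-reference coordinates.
#' @export
liftover_translocation <- function(pairs, chrom_a, chrom_b,
                                   breakpoint_a, breakpoint_b) {
  lift <- function(chrom, pos) {
    toB <- chrom == chrom_a & pos > breakpoint_a
    toA <- chrom == chrom_b & pos > breakpoint_b
    new_chrom <- chrom
    new_pos <- pos
    new_chrom[toB] <- chrom_b
    new_pos[toB] <- breakpoint_b + (pos[toB] - breakpoint_a)
    new_chrom[toA] <- chrom_a
    new_pos[toA] <- breakpoint_a + (pos[toA] - breakpoint_b)
    list(chrom = new_chrom, pos = new_pos)
  }
  e1 <- lift(pairs$chrom1, pairs$pos1)
  e2 <- lift(pairs$chrom2, pairs$pos2)
  data.frame(chrom1 = e1$chrom, pos1 = e1$pos,
             chrom2 = e2$chrom, pos2 = e2$pos, stringsAsFactors = FALSE)
}
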