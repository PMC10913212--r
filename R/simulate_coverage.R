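#' Simulate windowed parental-read coverage over a tetraploid reference
#'
#' Emulates mapping reads of one parental species onto the combined
#' tetraploid reference and averaging depth in fixed windows: windows lying
#' on the chromosomes (or HE segments) belonging to the parent's subgenome
#' receive depth Poisson(`depth_mean`); windows from the other subgenome
#' receive Poisson(`depth_mean * cross_mapping_rate`), modelling the small
#' fraction of reads that map to the wrong subgenome despite the divergence.
#'
#' @param genome Named character vector (tetraploid reference).
#' @param parent_label `"O"` or `"R"`.
#' @param window_size Window size in bp (default 10 kb).
#' @param depth_mean Mean on-target depth.
#' @param cross_mapping_rate Fraction in [0, 0.5) of depth reaching the
#'   wrong subgenome.
#' @param segments Optional segment source table (`chromosome`, `start`,
#'   `end`, `source`), e.g. `truth$he_segments`. Defaults to inferring the
#'   source from the chromosome name prefix; hybrid `O7_R7`-style names then
#'   require `segments`.
#' @param seed Integer RNG seed.
#'
#' @return A `depth_track`: list with `sample`, `window_size`, `values`
#'   (named list of per-chromosome numeric vectors) and `chrom_lengths`.
#' @export
simulate_parental_coverage <- function(genome, parent_label,
                                       window_size = 10000L,
                                       depth_mean = 30,
                                       cross_mapping_rate = 0.05,
                                       segments = NULL, seed = 1L) {
  stopifnot(parent_label %in% c("O", "R"))
  if (cross_mapping_rate < 0 || cross_mapping_rate >= 0.5)
    stop("cross_mapping_rate must be in [0, 0.5)")
  lens <- nchar(genome)
  if (window_size > min(lens))
    stop("window_size larger than the shortest chromosome")

  if (is.null(segments)) {
    if (any(grepl("_", names(genome), fixed = TRUE)))
      stop("hybrid chromosomes present: supply `segments` (truth$he_segments)")
    segments <- data.frame(chromosome = names(genome), start = 1L, end = lens,
                           source = substr(names(genome), 1L, 1L),
                           stringsAsFactors = FALSE)
  }

  with_seed_or_not(seed, {
    values <- vector("list", length(genome))
    names(values) <- names(genome)
    for (chrom in names(genome)) {
      L <- lens[[chrom]]
      starts <- seq(1L, L, by = window_size)
      mids <- pmin(starts + window_size %/% 2L, L)
      seg <- segments[segments$chromosome == chrom, ]
      src <- seg$source[findInterval(mids, seg$start)]
      lambda <- ifelse(src == parent_label, depth_mean,
                       depth_mean * cross_mapping_rate)
      values[[chrom]] <- rpois(length(starts), lambda)
    }
    structure(list(sample = parent_label, window_size = window_size,
                   values = values, chrom_lengths = lens),
              class = "depth_track")
  })
}

#' Combine two parental depth tracks into a per-chromosome coverage profile
#'
#' @param track_o,track_r `depth_track`s for the O and R parents on the same
#'   reference (same window size and chromosomes).
#' @param chromosome Chromosome name.
#' @return A `coverage_profile`: list with `chromosome`, `window_size`,
#'   `depth_O`, `depth_R`, `chrom_length`.
#' @export
coverage_profile <- function(track_o, track_r, chromosome) {
  stopifnot(track_o$window_size == track_r$window_size,
            chromosome %in% names(track_o$values),
            chromosome %in% names(track_r$values))
  o <- track_o$values[[chromosome]]; r <- track_r$values[[chromosome]]
  stopifnot(length(o) == length(r))
  structure(list(chromosome = chromosome,
                 window_size = track_o$window_size,
                 depth_O = as.numeric(o), depth_R = as.numeric(r),
                 chrom_length = track_o$chrom_lengths[[chromosome]]),
            class = "coverage_profile")
}
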