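#' Simulate an F2 mapping population with Poisson crossovers
#'
#' Each F2 plant receives two independent gametes per chromosome. A gamete is
#' a mosaic of the two parental haplotypes: the number of crossovers is drawn
#' from Poisson(`crossover_rate`) (no interference), crossover positions are
#' uniform along the chromosome, and the starting haplotype is random. The
#' genotype at a marker is the number of parent-2 allele copies (0/1/2).
#' Sequencing is emulated per plant and marker: total depth is
#' Poisson(`depth_mean`) and the reads supporting the parent-2 allele are
#' Binomial(depth, genotype/2), from which a genotype is called
#' (0 reads of one allele at nonzero depth collapses a heterozygote to a
#' homozygote call, as in real low-coverage data).
#'
#' @param parent1,parent2 Named character vectors of chromosome sequences
#'   (same names and lengths). Parent 1 plays the role of the reference
#'   accession; markers are the positions where parent 2 differs.
#' @param marker_positions Named list (per chromosome) of sorted positions at
#'   which the parents differ.
#' @param n_plants Number of F2 plants (>= 1).
#' @param crossover_rate Expected crossovers per chromosome per meiosis.
#' @param depth_mean Mean sequencing depth per marker.
#' @param seed Integer RNG seed.
#'
#' @return An `f2_cohort`: list with `markers` (data frame `chromosome`,
#'   `position`, `ref`, `alt`), `genotypes` (true 0/1/2, markers x plants),
#'   `depths`, `alt_reads`, `called` (0/1/2/NA from read evidence),
#'   `crossovers` (per plant, per chromosome numeric positions pooled over
#'   both gametes), `crossover_rate`, `n_plants`.
#' @export
simulate_f2 <- function(parent1, parent2, marker_positions, n_plants,
                        crossover_rate, depth_mean, seed = 1L) {
  stopifnot(n_plants >= 1)
  if (!identical(names(parent1), names(parent2)))
    stop("parents must have identical chromosome sets")
  for (chrom in names(marker_positions)) {
    pos <- marker_positions[[chrom]]
    L <- nchar(parent1[[chrom]])
    if (is.unsorted(pos, strictly = TRUE) || any(pos < 1) || any(pos > L))
      stop("marker positions must be sorted, unique and within range: ", chrom)
    b1 <- substring(parent1[[chrom]], pos, pos)
    b2 <- substring(parent2[[chrom]], pos, pos)
    if (any(b1 == b2))
      stop("parents do not differ at every marker position on ", chrom)
  }

  with_seed_or_not(seed, {
    chroms <- names(marker_positions)
    marker_df <- do.call(rbind, lapply(chroms, function(chrom) {
      pos <- marker_positions[[chrom]]
      data.frame(chromosome = chrom, position = as.integer(pos),
                 ref = substring(parent1[[chrom]], pos, pos),
                 alt = substring(parent2[[chrom]], pos, pos),
                 stringsAsFactors = FALSE)
    }))
    rownames(marker_df) <- paste0(marker_df$chromosome, ":", marker_df$position)
    n_mark <- nrow(marker_df)

    gamete <- function(pos, L) {
      nxo <- rpois(1L, crossover_rate)
      xo <- sort(runif(nxo, 0, L))
      start <- sample(0:1, 1L)
      list(alleles = (start + findInterval(pos, xo)) %% 2L, xo = xo)
    }

    genotypes <- matrix(0L, n_mark, n_plants,
                        dimnames = list(rownames(marker_df),
                                        paste0("plant_", seq_len(n_plants))))
    crossovers <- vector("list", n_plants)
    names(crossovers) <- colnames(genotypes)
    for (p in seq_len(n_plants)) {
      xo_p <- list()
      for (chrom in chroms) {
        pos <- marker_positions[[chrom]]
        L <- nchar(parent1[[chrom]])
        g1 <- gamete(pos, L); g2 <- gamete(pos, L)
        rows <- which(marker_df$chromosome == chrom)
        genotypes[rows, p] <- g1$alleles + g2$alleles
        xo_p[[chrom]] <- sort(c(g1$xo, g2$xo))
      }
      crossovers[[p]] <- xo_p
    }

    depths <- matrix(rpois(n_mark * n_plants, depth_mean), n_mark, n_plants,
                     dimnames = dimnames(genotypes))
    alt_reads <- matrix(rbinom(n_mark * n_plants, as.vector(depths),
                               as.vector(genotypes) / 2),
                        n_mark, n_plants, dimnames = dimnames(genotypes))
    called <- matrix(NA_integer_, n_mark, n_plants,
                     dimnames = dimnames(genotypes))
    nz <- depths > 0
    called[nz & alt_reads == 0L] <- 0L
    called[nz & alt_reads == depths] <- 2L
    called[nz & alt_reads > 0L & alt_reads < depths] <- 1L

    structure(list(markers = marker_df, genotypes = genotypes,
                   depths = depths, alt_reads = alt_reads, called = called,
                   crossovers = crossovers, crossover_rate = crossover_rate,
                   n_plants = n_plants),
              class = "f2_cohort")
  })
}

#' Mean observed crossovers per chromosome per meiosis in an F2 cohort
#'
#' @param cohort An `f2_cohort`.
#' @return Mean crossover count per chromosome per gamete (= per meiosis).
#' @export
mean_crossovers <- function(cohort) {
  counts <- unlist(lapply(cohort$crossovers, vapply, length, integer(1)))
  n_chrom <- length(cohort$crossovers[[1]])
  sum(counts) / (2 * cohort$n_plants * n_chrom)
}

#' Derive a polymorphic cross parent from a reference genome
#'
#' Substitutes a new allele at `markers_per_chrom` uniformly spaced (with
#' jitter) positions per chromosome, producing the second F0 parent of a
#' mapping cross together with the marker positions where the parents differ.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param markers_per_chrom Number of marker positions per chromosome.
#' @param seed Integer RNG seed.
#' @return List with `parent` (mutated genome) and `marker_positions`
#'   (named list of sorted positions per chromosome).
#' @export
make_cross_parent <- function(genome, markers_per_chrom, seed = 1L) {
  with_seed_or_not(seed, {
    parent <- genome
    marker_positions <- vector("list", length(genome))
    names(marker_positions) <- names(genome)
    for (chrom in names(genome)) {
      L <- nchar(genome[[chrom]])
      grid <- round(seq(L / (2 * markers_per_chrom), L,
                        length.out = markers_per_chrom))
      jitter <- round(runif(markers_per_chrom, -0.3, 0.3) *
                        (L / markers_per_chrom))
      pos <- as.integer(sort(unique(pmin(pmax(grid + jitter, 1L), L))))
      refb <- substring(genome[[chrom]], pos, pos)
      parent[[chrom]] <- substitute_bases(genome[[chrom]], pos,
                                          other_base(refb))
      marker_positions[[chrom]] <- pos
    }
    list(parent = parent, marker_positions = marker_positions)
  })
}

#' F0 parent-2 variant records relative to the parent-1 reference
#'
#' Emits the homozygous-alternative SNP records the second F0 parent shows
#' against the reference accession - the raw material for the homozygous
#' marker database. Coordinates can optionally be lifted onto contigs.
#'
#' @param cohort An `f2_cohort`.
#' @param contigs Optional contig segment table ([make_chimeric_contigs()]);
#'   when given, records are expressed in contig coordinates and carry
#'   `source_chrom` / `source_pos` columns linking back to cohort markers.
#' @param depth Reported DP for the F0 records.
#' @return Data frame with `contig`, `position`, `ref`, `alt`, `gt`, `dp`
#'   (+ source columns if lifted).
#' @export
f0_variant_records <- function(cohort, contigs = NULL, depth = 30L) {
  mk <- cohort$markers
  if (is.null(contigs)) {
    out <- data.frame(contig = mk$chromosome, position = mk$position,
                      ref = mk$ref, alt = mk$alt, gt = "1/1", dp = depth,
                      source_chrom = mk$chromosome, source_pos = mk$position,
                      stringsAsFactors = FALSE)
    return(out[order(out$contig, out$position), ])
  }
  lifted <- lift_to_contigs(contigs, mk$chromosome, mk$position)
  key <- paste0(lifted$chromosome, ":", lifted$chrom_pos)
  data.frame(contig = lifted$contig, position = lifted$position,
             ref = mk[key, "ref"], alt = mk[key, "alt"],
             gt = "1/1", dp = depth,
             source_chrom = lifted$chromosome, source_pos = lifted$chrom_pos,
             stringsAsFactors = FALSE)
}
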