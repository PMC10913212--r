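#' Simulate a synthetic allotetraploid with full ground truth
#'
#' Builds a miniature allotetraploid the way *Capsella bursa-pastoris*-like
#' genomes arise: a common ancestor is simulated, two subgenomes (O and R)
#' diverge from it by substitution at a fixed per-bp rate, and the tetraploid
#' reference is the union of the two chromosome sets. Optionally one
#' homeologous chromosome pair undergoes a reciprocal homeologous exchange
#' (HE), producing two hybrid chromosomes whose source subgenome switches at
#' the breakpoint (named e.g. `O7_R7` / `R7_O7`).
#'
#' Divergence is substitution-only, so homeologous coordinates are identical
#' between subgenomes and ground-truth bookkeeping is exact. The O subgenome
#' equals the ancestor; every divergence substitution is placed on the R
#' branch (the variant count is still Binomial(length, rate) per chromosome).
#'
#' @param n_chromosomes Number of chromosomes per subgenome (>= 1).
#' @param chrom_length Chromosome length in bp; at least 100 kb (10 windows
#'   of the standard 10-kb analysis window).
#' @param divergence_snp_rate Per-bp substitution probability between the
#'   subgenomes, in (0, 0.2).
#' @param he_spec Optional reciprocal-exchange descriptor:
#'   `list(chromosome = <index>, fraction = <breakpoint fraction in (0,1)>)`.
#' @param deleted_region Optional `list(chromosome = <index>, start, end)`;
#'   the corresponding interval of the O-subgenome chromosome is replaced by
#'   non-homologous random sequence (a synthetic analog of a lineage-specific
#'   deletion: coordinates stay aligned but homology is absent).
#' @param seed Integer RNG seed.
#'
#' @return A list with components:
#'   * `pair`: the subgenome pair (`genomeO`, `genomeR` named character
#'     vectors, `divergence_snp_rate`, `variants` data frame with
#'     `chromosome`, `position`, `alleleO`, `alleleR`).
#'   * `reference`: the tetraploid reference, a named character vector of
#'     `2 * n_chromosomes` chromosomes.
#'   * `truth`: a `truth_set` recording HE breakpoints and segment sources,
#'     planted variants and the deleted region.
#' @export
simulate_allotetraploid <- function(n_chromosomes, chrom_length,
                                    divergence_snp_rate,
                                    he_spec = NULL,
                                    deleted_region = NULL,
                                    seed = 1L) {
  stopifnot(n_chromosomes >= 1)
  if (divergence_snp_rate <= 0 || divergence_snp_rate >= 0.2)
    stop("divergence_snp_rate must be in (0, 0.2)")
  if (chrom_length < 10L * 10000L)
    stop("degenerate chromosome length: need at least 10 windows of 10 kb")
  if (!is.null(he_spec)) {
    if (he_spec$chromosome < 1 || he_spec$chromosome > n_chromosomes)
      stop("he_spec chromosome index out of range")
    if (he_spec$fraction <= 0 || he_spec$fraction >= 1)
      stop("he_spec breakpoint fraction must be in (0, 1)")
  }

  with_seed_or_not(seed, {
    chromO <- character(n_chromosomes)
    chromR <- character(n_chromosomes)
    variants <- vector("list", n_chromosomes)
    for (i in seq_len(n_chromosomes)) {
      anc <- random_chromosome(chrom_length)
      pos <- which(runif(chrom_length) < divergence_snp_rate)
      ancChars <- substring(anc, pos, pos)
      alt <- other_base(ancChars)
      chromO[i] <- anc
      chromR[i] <- substitute_bases(anc, pos, alt)
      variants[[i]] <- data.frame(chromosome = rep(i, length(pos)),
                                  position = pos,
                                  alleleO = ancChars, alleleR = alt,
                                  stringsAsFactors = FALSE)
    }
    names(chromO) <- paste0("O", seq_len(n_chromosomes))
    names(chromR) <- paste0("R", seq_len(n_chromosomes))
    variants <- do.call(rbind, variants)

    del_df <- NULL
    if (!is.null(deleted_region)) {
      i <- deleted_region$chromosome
      s <- deleted_region$start; e <- deleted_region$end
      if (s < 1 || e > chrom_length || s >= e)
        stop("deleted_region outside chromosome bounds")
      repl <- random_chromosome(e - s + 1L)
      chromO[i] <- paste0(substr(chromO[i], 1L, s - 1L), repl,
                          substr(chromO[i], e + 1L, chrom_length))
      del_df <- data.frame(chromosome = paste0("O", i), start = s, end = e,
                           stringsAsFactors = FALSE)
    }

    reference <- c(chromO, chromR)
    seg <- data.frame(chromosome = names(reference), start = 1L,
                      end = chrom_length,
                      source = rep(c("O", "R"), each = n_chromosomes),
                      stringsAsFactors = FALSE)
    he_df <- data.frame(chromosome = character(0), position = integer(0))

    if (!is.null(he_spec)) {
      i <- he_spec$chromosome
      bp <- floor(he_spec$fraction * chrom_length)
      o <- chromO[i]; r <- chromR[i]
      nmO <- paste0("O", i, "_R", i)
      nmR <- paste0("R", i, "_O", i)
      hyO <- paste0(substr(o, 1L, bp), substr(r, bp + 1L, chrom_length))
      hyR <- paste0(substr(r, 1L, bp), substr(o, bp + 1L, chrom_length))
      names(reference)[match(paste0("O", i), names(reference))] <- nmO
      names(reference)[match(paste0("R", i), names(reference))] <- nmR
      reference[nmO] <- hyO
      reference[nmR] <- hyR
      he_df <- data.frame(chromosome = c(nmO, nmR), position = bp,
                          stringsAsFactors = FALSE)
      seg <- seg[!(seg$chromosome %in% c(paste0("O", i), paste0("R", i))), ]
      seg <- rbind(seg, data.frame(
        chromosome = rep(c(nmO, nmR), each = 2),
        start = rep(c(1L, bp + 1L), 2),
        end = rep(c(bp, chrom_length), 2),
        source = c("O", "R", "R", "O"),
        stringsAsFactors = FALSE))
      rownames(seg) <- NULL
    }

    truth <- structure(list(
      variants = variants,
      he_breakpoints = he_df,
      he_segments = seg,
      chimera_junctions = NULL,
      crossovers = NULL,
      homeolog_pairs = NULL,
      deleted_region = del_df,
      chrom_length = chrom_length,
      seed = seed), class = "truth_set")

    pair <- structure(list(genomeO = chromO, genomeR = chromR,
                           divergence_snp_rate = divergence_snp_rate,
                           variants = variants), class = "subgenome_pair")

    list(pair = pair, reference = reference, truth = truth)
  })
}

#' Cut a genome into contigs and plant chimeric joins
#'
#' Chromosomes are cut into `n_contigs_per_chrom` contigs (breakpoints
#' jittered around an even grid). `n_chimeras` contigs derived from pure
#' O-subgenome chromosomes are then each replaced by a chimera joining their
#' first half to the second half of the positionally matching contig on the
#' homeologous R chromosome - the kind of join expected between highly
#' similar subgenomes. Junction coordinates are recorded in the truth set.
#'
#' Before chimera injection the contigs tile the genome exactly (no bases
#' lost). Hybrid HE chromosomes are excluded from chimera sampling because
#' their homeolog is position-dependent.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n_contigs_per_chrom Contigs per chromosome (>= 1).
#' @param n_chimeras Number of chimeric contigs to plant.
#' @param truth Optional `truth_set` to update with `chimera_junctions`.
#' @param seed Integer RNG seed.
#'
#' @return List with `contigs` (segment table: `contig`, `piece`,
#'   `chromosome`, `start`, `end` - one row per source segment),
#'   `sequences` (named character vector of contig sequences) and `truth`
#'   (updated truth set; `chimera_junctions` has `contig`, `position`,
#'   `partner_contig`).
#' @export
make_chimeric_contigs <- function(genome, n_contigs_per_chrom, n_chimeras = 0L,
                                  truth = NULL, seed = 1L) {
  if (n_contigs_per_chrom < 1) stop("n_contigs_per_chrom must be >= 1")
  with_seed_or_not(seed, {
    segs <- list()
    for (chrom in names(genome)) {
      L <- nchar(genome[[chrom]])
      k <- n_contigs_per_chrom
      cuts <- round(seq(0, L, length.out = k + 1L))
      if (k > 1L) {
        jitter <- round(runif(k - 1L, -0.2, 0.2) * (L / k))
        cuts[2:k] <- pmin(pmax(cuts[2:k] + jitter, seq_len(k - 1L) * 2L),
                          L - rev(seq_len(k - 1L)) * 2L)
        cuts <- sort(cuts)
      }
      segs[[chrom]] <- data.frame(
        contig = sprintf("ctg_%s_%02d", chrom, seq_len(k)),
        piece = 1L,
        chromosome = chrom,
        start = cuts[-(k + 1L)] + 1L,
        end = cuts[-1L],
        stringsAsFactors = FALSE)
    }
    contigs <- do.call(rbind, segs)
    rownames(contigs) <- NULL

    # eligible chimera hosts: contigs on pure O chromosomes whose homeologous
    # R chromosome is also pure
    pureO <- grep("^O[0-9]+$", names(genome), value = TRUE)
    eligible <- contigs[contigs$chromosome %in% pureO, ]
    eligible <- eligible[paste0("R", sub("^O", "", eligible$chromosome)) %in%
                           names(genome), ]
    if (n_chimeras > nrow(eligible))
      stop("n_chimeras exceeds the number of eligible contig pairs")

    junctions <- data.frame(contig = character(0), position = integer(0),
                            partner_contig = character(0),
                            stringsAsFactors = FALSE)
    if (n_chimeras > 0L) {
      pick <- eligible[sample(nrow(eligible), n_chimeras), , drop = FALSE]
      for (j in seq_len(nrow(pick))) {
        host <- pick[j, ]
        rchrom <- paste0("R", sub("^O", "", host$chromosome))
        ord <- as.integer(sub(".*_([0-9]+)$", "\\1", host$contig))
        partner <- contigs[contigs$chromosome == rchrom & contigs$piece == 1L, ]
        partner <- partner[order(partner$start), ][ord, ]
        midO <- host$start + floor((host$end - host$start) / 2L)
        midR <- partner$start + floor((partner$end - partner$start) / 2L)
        idx <- which(contigs$contig == host$contig)
        contigs[idx, "end"] <- midO
        contigs <- rbind(contigs, data.frame(
          contig = host$contig, piece = 2L, chromosome = rchrom,
          start = midR + 1L, end = partner$end, stringsAsFactors = FALSE))
        junctions <- rbind(junctions, data.frame(
          contig = host$contig, position = midO - host$start + 1L,
          partner_contig = partner$contig, stringsAsFactors = FALSE))
      }
      contigs <- contigs[order(contigs$contig, contigs$piece), ]
      rownames(contigs) <- NULL
    }

    seqs <- vapply(split(contigs, contigs$contig), function(df) {
      df <- df[order(df$piece), ]
      paste(substr(rep(genome[df$chromosome], 1L), df$start, df$end),
            collapse = "")
    }, character(1))

    if (!is.null(truth)) truth$chimera_junctions <- junctions
    list(contigs = contigs, sequences = seqs,
         truth = truth %||% structure(list(chimera_junctions = junctions),
                                      class = "truth_set"))
  })
}

#' Map chromosome positions onto contig coordinates
#'
#' Positions falling inside a chimeric contig's foreign piece are mapped
#' there too, so a chromosome position may yield more than one contig
#' location.
#'
#' @param contigs Contig segment table from [make_chimeric_contigs()].
#' @param chromosome,position Parallel vectors of chromosome coordinates.
#' @return Data frame `contig`, `position` (contig coordinate), `chromosome`,
#'   `chrom_pos` (the input coordinate).
#' @export
lift_to_contigs <- function(contigs, chromosome, position) {
  # offset of each segment inside its contig = total length of earlier pieces
  seglen <- contigs$end - contigs$start + 1L
  offset <- integer(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    earlier <- contigs$contig == contigs$contig[i] &
      contigs$piece < contigs$piece[i]
    offset[i] <- sum(seglen[earlier])
  }
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    hit <- which(chromosome == contigs$chromosome[i] &
                   position >= contigs$start[i] & position <= contigs$end[i])
    if (length(hit) == 0L) return(NULL)
    data.frame(contig = contigs$contig[i],
               position = position[hit] - contigs$start[i] + 1L + offset[i],
               chromosome = chromosome[hit],
               chrom_pos = position[hit],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$contig, res$position), , drop = FALSE]
}
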