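#' Simulate a homeologous chromosome pair with annotated gene models
#'
#' Plants `n_genes` valid ORFs at matching coordinates on one O and one R
#' chromosome. Gene and intergenic sequence diverge between the subgenomes
#' at `divergence` per bp; within genes the substitutions are resampled so
#' that no internal in-frame stop is created (both copies stay valid ORFs,
#' as surviving homeolog pairs do). Two kinds of gaps can be planted to
#' exercise downstream pairing:
#'
#' * `omit_idx`: genes removed from the **R annotation** while the sequence
#'   remains in the R genome - recoverable by interval-constrained rescue.
#' * `deleted_idx`: genes removed from the **O annotation** whose O locus is
#'   additionally replaced by non-homologous random sequence (the analog of
#'   a lineage-specific deletion) - genuinely missing, not rescuable.
#'
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Genes per chromosome.
#' @param gene_length CDS length in bp (multiple of 3, default 900).
#' @param divergence Per-bp substitution rate between subgenomes.
#' @param omit_idx,deleted_idx Integer gene indices (1..n_genes).
#' @param chrom_index Chromosome number used in the names (`O<i>`, `R<i>`).
#' @param seed Integer RNG seed.
#' @return List with `genomeO`, `genomeR` (single-chromosome named character
#'   vectors), `annotO`, `annotR` (gene model tables), and `truth`: list
#'   with `pairs` (data frame `geneR`, `geneO` of genes annotated on both
#'   sides), `rescuable` (O gene ids whose R partner is unannotated) and
#'   `missing` (R gene ids whose O locus was deleted).
#' @export
simulate_gene_models <- function(chrom_length, n_genes, gene_length = 900L,
                                 divergence = 0.01,
                                 omit_idx = integer(0),
                                 deleted_idx = integer(0),
                                 chrom_index = 1L, seed = 1L) {
  stopifnot(gene_length %% 3L == 0L, gene_length >= 6L,
            n_genes * 2L * gene_length < chrom_length)
  stopifnot(all(omit_idx %in% seq_len(n_genes)),
            all(deleted_idx %in% seq_len(n_genes)),
            length(intersect(omit_idx, deleted_idx)) == 0L)

  with_seed_or_not(seed, {
    chromO_name <- paste0("O", chrom_index)
    chromR_name <- paste0("R", chrom_index)

    # diverged background
    bgO <- random_chromosome(chrom_length)
    pos <- which(runif(chrom_length) < divergence)
    bgR <- substitute_bases(bgO, pos, other_base(substring(bgO, pos, pos)))

    spacing <- chrom_length / n_genes
    starts <- round((seq_len(n_genes) - 0.5) * spacing - gene_length / 2)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    orfO <- vapply(seq_len(n_genes), function(i) random_orf(gene_length),
                   character(1))
    orfR <- vapply(orfO, mutate_orf, character(1), rate = divergence,
                   USE.NAMES = FALSE)

    plant <- function(bg, orfs, skip_random = integer(0)) {
      for (i in seq_len(n_genes)) {
        s <- starts[i]; e <- s + gene_length - 1L
        insert <- if (i %in% skip_random) random_chromosome(gene_length)
                  else if (strands[i] == "-") revcomp(orfs[i]) else orfs[i]
        bg <- paste0(substr(bg, 1L, s - 1L), insert,
                     substr(bg, e + 1L, chrom_length))
      }
      bg
    }
    genomeO <- stats::setNames(plant(bgO, orfO, skip_random = deleted_idx),
                               chromO_name)
    genomeR <- stats::setNames(plant(bgR, orfR), chromR_name)

    idO <- sprintf("g%s_%03d", chromO_name, seq_len(n_genes))
    idR <- sprintf("g%s_%03d", chromR_name, seq_len(n_genes))
    model <- function(ids, chrom) data.frame(
      id = ids, chromosome = chrom, start = starts,
      end = starts + gene_length - 1L, strand = strands,
      stringsAsFactors = FALSE)
    annotO <- model(idO, chromO_name)[setdiff(seq_len(n_genes), deleted_idx), ]
    annotR <- model(idR, chromR_name)[setdiff(seq_len(n_genes), omit_idx), ]
    rownames(annotO) <- rownames(annotR) <- NULL

    both <- setdiff(seq_len(n_genes), union(omit_idx, deleted_idx))
    truth <- list(
      pairs = data.frame(geneR = idR[both], geneO = idO[both],
                         stringsAsFactors = FALSE),
      rescuable = idO[omit_idx],
      missing = idR[deleted_idx])

    list(genomeO = genomeO, genomeR = genomeR,
         annotO = annotO, annotR = annotR, truth = truth)
  })
}

# A random valid ORF: ATG + non-stop codons + one stop.
random_orf <- function(length) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                      paste, collapse = "")
  sense <- setdiff(all_codons, stops)
  n_mid <- length %/% 3L - 2L
  paste0("ATG", paste(sample(sense, n_mid, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

# Substitute bases at `rate`, never touching the start/stop codons and
# resampling any substitution that would create an internal in-frame stop.
mutate_orf <- function(orf, rate) {
  n <- nchar(orf)
  chars <- strsplit(orf, "", fixed = TRUE)[[1]]
  stops <- c("TAA", "TAG", "TGA")
  pos <- which(runif(n) < rate)
  pos <- pos[pos > 3L & pos <= n - 3L]
  for (p in pos) {
    c0 <- (p - 1L) %/% 3L  # 0-based codon index
    cand <- setdiff(DNA_BASES, chars[p])
    ok <- vapply(cand, function(b) {
      tmp <- chars[(c0 * 3L + 1L):(c0 * 3L + 3L)]
      tmp[p - c0 * 3L] <- b
      !(paste(tmp, collapse = "") %in% stops)
    }, logical(1))
    if (any(ok)) chars[p] <- sample(rep(cand[ok], 2L), 1L)
  }
  paste(chars, collapse = "")
}
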