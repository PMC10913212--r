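#' Union list of variable positions across samples
#'
#' Every biallelic SNP found in at least one sample enters the list; indels
#' are excluded. Sites where samples disagree on the alternative allele are
#' kept and logged (attribute `"conflicts"`).
#'
#' @param sample_variants Named list of per-sample variant tables with
#'   columns `chrom`, `pos`, `ref`, `alt`.
#' @return Data frame `chrom`, `pos`, `ref`, `alt` (the first-seen alt),
#'   sorted; attribute `"conflicts"` lists multi-alt sites.
#' @export
build_site_list <- function(sample_variants) {
  all <- do.call(rbind, lapply(sample_variants, function(v) {
    snp <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
      v$ref %in% DNA_BASES & v$alt %in% DNA_BASES
    v[snp, c("chrom", "pos", "ref", "alt")]
  }))
  if (is.null(all) || nrow(all) == 0L)
    return(structure(data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0)),
                     conflicts = character(0)))
  key <- paste0(all$chrom, ":", all$pos)
  n_alt <- vapply(split(all$alt, key), function(a) length(unique(a)),
                  integer(1))
  conflicts <- names(n_alt)[n_alt > 1L]
  if (length(conflicts))
    message("build_site_list: ", length(conflicts),
            " site(s) with conflicting alt alleles (kept)")
  sites <- all[!duplicated(key), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "conflicts") <- conflicts
  sites
}

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Output base for a sample at a listed site
#'
#' Implements the pseudoalignment substitution rule: depth below
#' `min_depth` masks the site as `N`; a homozygous-alternative call emits
#' the alternative base; a heterozygous call emits the two-base IUPAC
#' ambiguity code (R = A/G, Y = C/T, S = G/C, W = A/T, K = G/T, M = A/C);
#' no call at adequate depth emits the reference base. Vectorised.
#'
#' @param ref_base,alt_base Reference / alternative alleles (`alt_base` may
#'   be NA when there is no call).
#' @param gt Genotype string (`"0/0"`, `"0/1"`, `"1/1"`, ...) or NA for no
#'   call.
#' @param depth Read depth at the site.
#' @param min_depth Masking threshold (default 4).
#' @return Character vector of output bases.
#' @export
genotype_to_base <- function(ref_base, alt_base, gt, depth, min_depth = 4L) {
  n <- max(length(ref_base), length(alt_base), length(gt), length(depth))
  ref_base <- rep_len(ref_base, n); alt_base <- rep_len(alt_base, n)
  gt <- rep_len(gt, n); depth <- rep_len(depth, n)
  if (!all(ref_base %in% DNA_BASES)) stop("reference base outside {A,C,G,T}")
  called <- !is.na(gt)
  if (any(called & !(alt_base %in% c(DNA_BASES, NA))))
    stop("genotype cites a base outside {A,C,G,T}")
  out <- ref_base
  hom <- called & gt %in% c("1/1", "1|1")
  het <- called & gt %in% c("0/1", "0|1", "1|0", "1/0")
  out[hom] <- alt_base[hom]
  if (any(het)) {
    pair <- vapply(which(het), function(i)
      paste(sort(c(ref_base[i], alt_base[i])), collapse = ""), character(1))
    code <- IUPAC2[pair]
    if (anyNA(code)) stop("invalid heterozygote allele pair")
    out[het] <- code
  }
  out[depth < min_depth] <- "N"
  out
}

#' Build a multi-sample pseudoalignment for a reference region
#'
#' Each sample sequence is the reference region with the sample's SNPs
#' substituted under the [genotype_to_base()] rules; non-site positions stay
#' reference, so the rows are positionally homologous by construction. The
#' reference itself is always the first record.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param region List or data frame row with `chrom`, `start`, `end`
#'   (1-based, closed) - typically a chromosome arm.
#' @param sites Site list ([build_site_list()]) restricted to the reference;
#'   sites outside the region are an error.
#' @param samples Named list of per-sample call tables (`chrom`, `pos`,
#'   `ref`, `alt`, `gt`, `dp`). A sample with no call at a listed site emits
#'   the reference base unless `site_depths` marks it low-coverage.
#' @param site_depths Optional sites x samples depth matrix (rows keyed
#'   `chrom:pos`) giving depth at sites absent from a sample's calls;
#'   defaults to adequate depth.
#' @param min_depth Masking threshold (default 4).
#' @return A `pseudoalignment`: list with `sequences` (named character
#'   vector, reference first), `region`, `sites_used`.
#' @export
build_pseudoalignment <- function(reference, region, sites, samples = list(),
                                  site_depths = NULL, min_depth = 4L) {
  chrom <- region$chrom
  if (!chrom %in% names(reference)) stop("region chromosome not in reference")
  L <- nchar(reference[[chrom]])
  if (region$start < 1L || region$end > L || region$start > region$end)
    stop("region outside reference bounds")
  use <- sites[sites$chrom == chrom, , drop = FALSE]
  if (any(use$pos < region$start | use$pos > region$end))
    stop("site list contains positions outside the region")
  ref_seq <- substr(reference[[chrom]], region$start, region$end)
  site_key <- paste0(use$chrom, ":", use$pos)
  rel <- use$pos - region$start + 1L

  seqs <- c(reference = ref_seq)
  for (s in names(samples)) {
    calls <- samples[[s]]
    m <- match(site_key, paste0(calls$chrom, ":", calls$pos))
    gt <- calls$gt[m]; alt <- calls$alt[m]; dp <- calls$dp[m]
    if (!is.null(site_depths) && s %in% colnames(site_depths)) {
      d0 <- site_depths[site_key, s]
      dp[is.na(m)] <- d0[is.na(m)]
    } else {
      dp[is.na(m)] <- min_depth  # assume adequate coverage when unstated
    }
    bases <- genotype_to_base(use$ref, alt, gt, dp, min_depth)
    seqs[s] <- substitute_bases(ref_seq, rel, bases)
  }
  structure(list(sequences = seqs, region = region, sites_used = use),
            class = "pseudoalignment")
}

IUPAC_ALLELES <- list(A = c("A", "A"), C = c("C", "C"), G = c("G", "G"),
                      T = c("T", "T"),
                      M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                      S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))

#' Patterson's D (ABBA-BABA) and f4-ratio with block jackknife
#'
#' With per-site derived-allele frequencies p1, p2, p3 in populations
#' (P1, P2, P3) and the outgroup fixed for the ancestral allele,
#' `D = sum((1-p1) p2 p3 - p1 (1-p2) p3) / sum((1-p1) p2 p3 + p1 (1-p2) p3)`.
#' Z is D over its block-jackknife standard error (blocks of `block_size`
#' consecutive used sites). The f4-ratio splits P3 into two halves (P3a,
#' P3b) and estimates the admixed ancestry fraction as the ratio of the
#' ABBA-BABA numerator computed with P2 to the one computed with P3b in
#' P2's place.
#'
#' Input is either an alignment (named sequences over ACGTN + IUPAC codes;
#' heterozygotes contribute allele frequency 0.5) with a `groups` mapping,
#' or a numeric matrix/data frame of derived-allele frequencies with columns
#' `p1`, `p2`, `p3` (optionally `p3a`, `p3b`).
#'
#' @param x A `pseudoalignment`, named character vector of aligned
#'   sequences, or frequency matrix.
#' @param groups For sequence input: named list
#'   `list(P1 = <sample names>, P2 = ..., P3 = ..., O = ...)`.
#' @param block_size Jackknife block size in used sites (default 1000).
#' @return A `d_result`: list with `D`, `Z`, `f4_ratio`, `nABBA`, `nBABA`
#'   (the frequency-weighted sums), `n_sites`, `n_blocks`.
#' @export
patterson_d <- function(x, groups = NULL, block_size = 1000L) {
  if (inherits(x, "pseudoalignment")) x <- x$sequences
  if (is.character(x)) {
    stopifnot(!is.null(groups), all(c("P1", "P2", "P3", "O") %in% names(groups)))
    freqs <- alignment_frequencies(x, groups)
  } else {
    freqs <- as.data.frame(x)
    stopifnot(all(c("p1", "p2", "p3") %in% colnames(freqs)))
  }
  p1 <- freqs$p1; p2 <- freqs$p2; p3 <- freqs$p3
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  num <- abba - baba; den <- abba + baba
  if (sum(den) == 0) {
    return(structure(list(D = NA_real_, Z = NA_real_, f4_ratio = NA_real_,
                          nABBA = 0, nBABA = 0, n_sites = length(p1),
                          n_blocks = 0L), class = "d_result"))
  }
  D <- sum(num) / sum(den)

  n <- length(num)
  blocks <- ceiling(seq_len(n) / block_size)
  m <- max(blocks)
  Z <- NA_real_
  if (m >= 2L) {
    bnum <- tapply(num, blocks, sum); bden <- tapply(den, blocks, sum)
    Dj <- (sum(num) - bnum) / (sum(den) - bden)
    Dj <- Dj[is.finite(Dj)]
    mm <- length(Dj)
    if (mm >= 2L) {
      se <- sqrt((mm - 1) / mm * sum((Dj - mean(Dj))^2))
      if (se > 0) Z <- D / se
    }
  }

  f4r <- NA_real_
  if (all(c("p3a", "p3b") %in% colnames(freqs))) {
    p3a <- freqs$p3a; p3b <- freqs$p3b
    den_f <- sum((1 - p1) * p3b * p3a - p1 * (1 - p3b) * p3a)
    num_f <- sum((1 - p1) * p2 * p3a - p1 * (1 - p2) * p3a)
    if (den_f != 0) f4r <- num_f / den_f
  }

  structure(list(D = D, Z = Z, f4_ratio = f4r,
                 nABBA = sum(abba), nBABA = sum(baba),
                 n_sites = n, n_blocks = m), class = "d_result")
}

# Per-site derived-allele frequencies from aligned sequences.
# The outgroup's major allele is ancestral; sites are used when biallelic
# across the four groups, the outgroup is fixed, and no group is entirely N.
alignment_frequencies <- function(seqs, groups) {
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  len <- unique(lengths(chars))
  if (length(len) != 1L) stop("sequences are not aligned (unequal lengths)")
  grp <- function(g) chars[groups[[g]]]

  split_p3 <- length(groups$P3) >= 2L
  p3a_ids <- if (split_p3) groups$P3[seq_len(length(groups$P3) %/% 2L)] else NULL
  p3b_ids <- if (split_p3) setdiff(groups$P3, p3a_ids) else NULL

  freq_of <- function(members, i, derived) {
    al <- unlist(lapply(members, function(ch) IUPAC_ALLELES[[ch[i]]]))
    al <- al[!is.na(al)]
    if (length(al) == 0L) return(NA_real_)
    mean(al == derived)
  }

  rows <- vector("list", len)
  gO <- grp("O"); g1 <- grp("P1"); g2 <- grp("P2"); g3 <- grp("P3")
  g3a <- if (split_p3) chars[p3a_ids] else NULL
  g3b <- if (split_p3) chars[p3b_ids] else NULL
  used <- 0L
  for (i in seq_len(len)) {
    allb <- unlist(lapply(c(gO, g1, g2, g3), function(ch) {
      IUPAC_ALLELES[[ch[i]]]
    }))
    allb <- allb[!is.na(allb)]
    ub <- unique(allb)
    if (length(ub) != 2L) next
    anc_alleles <- unlist(lapply(gO, function(ch) IUPAC_ALLELES[[ch[i]]]))
    anc_alleles <- anc_alleles[!is.na(anc_alleles)]
    if (length(anc_alleles) == 0L || length(unique(anc_alleles)) != 1L) next
    anc <- anc_alleles[1]
    der <- setdiff(ub, anc)
    if (length(der) != 1L) next
    p1 <- freq_of(g1, i, der); p2 <- freq_of(g2, i, der)
    p3 <- freq_of(g3, i, der)
    if (anyNA(c(p1, p2, p3))) next  # a group entirely N
    used <- used + 1L
    row <- c(p1 = p1, p2 = p2, p3 = p3)
    if (split_p3) {
      p3a <- freq_of(g3a, i, der); p3b <- freq_of(g3b, i, der)
      if (anyNA(c(p3a, p3b))) next
      row <- c(row, p3a = p3a, p3b = p3b)
    }
    rows[[used]] <- row
  }
  if (used == 0L)
    return(data.frame(p1 = numeric(0), p2 = numeric(0), p3 = numeric(0)))
  as.data.frame(do.call(rbind, rows[seq_len(used)]))
}
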