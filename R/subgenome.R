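#' Per-window log ratio of parental coverage
#'
#' Quantifies the parental-coverage contrast along a chromosome:
#' `log2((depth_O + pc) / (depth_R + pc))`. Positive windows favour the O
#' parent, negative windows the R parent.
#'
#' @param profile A `coverage_profile`.
#' @param pseudocount Added to both depths (default 1) to keep values finite.
#' @return Numeric vector, one value per window.
#' @export
window_log_ratio <- function(profile, pseudocount = 1) {
  stopifnot(length(profile$depth_O) > 0L)
  log2((profile$depth_O + pseudocount) / (profile$depth_R + pseudocount))
}

#' Call the subgenome of origin of a chromosome from parental coverage
#'
#' Segments the per-window coverage log-ratio by recursive binary
#' segmentation (each split minimises the within-segment squared error; a
#' split is accepted while the two side means differ by at least
#' `min_abs_log_ratio` and both sides span `min_segment_windows`), labels
#' each segment O or R by its mean sign, and merges same-label neighbours.
#' A chromosome whose segments all share one source is called `O` or `R`;
#' two sources make it `hybrid` (a homeologous-exchange chromosome) with
#' the segment boundaries reported as breakpoints; a track whose windows are
#' all ambiguous (|log-ratio| below `min_abs_log_ratio`) is `unassigned`.
#'
#' @param profile A `coverage_profile`.
#' @param min_abs_log_ratio Decisiveness threshold on the log-ratio
#'   (default 1, i.e. a 2-fold coverage bias).
#' @param min_segment_windows Minimum windows per segment (default 5).
#' @param pseudocount Passed to [window_log_ratio()].
#' @return A `subgenome_call`: list with `chromosome`, `label`
#'   (`"O"|"R"|"hybrid"|"unassigned"`), `segments` (data frame `start`,
#'   `end` in bp, `source`), `breakpoints` (bp positions), `confidence`
#'   (fraction of windows decisively agreeing with their segment label).
#' @export
call_subgenome <- function(profile, min_abs_log_ratio = 1,
                           min_segment_windows = 5L, pseudocount = 1) {
  lr <- window_log_ratio(profile, pseudocount)
  nw <- length(lr)
  if (nw < min_segment_windows)
    stop("chromosome shorter than min_segment_windows windows")
  ws <- profile$window_size
  len <- profile$chrom_length %||% (nw * ws)

  if (all(abs(lr) < min_abs_log_ratio)) {
    return(structure(list(chromosome = profile$chromosome,
                          label = "unassigned",
                          segments = data.frame(start = 1L, end = len,
                                                source = NA_character_),
                          breakpoints = numeric(0), confidence = 0),
                     class = "subgenome_call"))
  }

  # recursive binary segmentation on window indices
  segment_bounds <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * min_segment_windows) return(integer(0))
    x <- lr[lo:hi]
    csum <- cumsum(x); csq <- cumsum(x^2)
    ks <- min_segment_windows:(n - min_segment_windows)
    sseL <- csq[ks] - csum[ks]^2 / ks
    sseR <- (csq[n] - csq[ks]) - (csum[n] - csum[ks])^2 / (n - ks)
    k <- ks[which.min(sseL + sseR)]
    meanL <- csum[k] / k
    meanR <- (csum[n] - csum[k]) / (n - k)
    if (abs(meanL - meanR) < min_abs_log_ratio) return(integer(0))
    cut <- lo + k - 1L  # last window of the left segment
    c(segment_bounds(lo, cut), cut, segment_bounds(cut + 1L, hi))
  }
  cuts <- segment_bounds(1L, nw)
  starts_w <- c(1L, cuts + 1L)
  ends_w <- c(cuts, nw)
  means <- mapply(function(s, e) mean(lr[s:e]), starts_w, ends_w)
  source <- ifelse(means > 0, "O", "R")

  # merge adjacent same-source segments
  keep <- c(TRUE, source[-1] != source[-length(source)])
  starts_w <- starts_w[keep]
  ends_w <- c(starts_w[-1] - 1L, nw)
  source <- source[keep]

  seg_bp <- data.frame(
    start = (starts_w - 1L) * ws + 1L,
    end = pmin(ends_w * ws, len),
    source = source, stringsAsFactors = FALSE)
  breakpoints <- if (nrow(seg_bp) > 1L) seg_bp$end[-nrow(seg_bp)] else numeric(0)

  win_src <- rep(source, ends_w - starts_w + 1L)
  decisive <- abs(lr) >= min_abs_log_ratio
  agree <- decisive & ((lr > 0) == (win_src == "O"))
  label <- if (length(unique(source)) > 1L) "hybrid" else source[1]

  structure(list(chromosome = profile$chromosome, label = label,
                 segments = seg_bp, breakpoints = breakpoints,
                 confidence = mean(agree)),
            class = "subgenome_call")
}

#' Validate subgenome separability by simulated read assignment
#'
#' Emulates the mapping-based check of subgenome assignment: reads are
#' sampled from one parental genome and assigned to the chromosome of the
#' combined (tetraploid) reference sharing the most diagnostic exact k-mers
#' (k-mers occurring in a single reference chromosome; ties or no diagnostic
#' k-mer leave the read unassigned). Reports the fraction of reads assigned
#' to the correct subgenome, per parent.
#'
#' @param pair A `subgenome_pair` (provides the parental genomes).
#' @param combined_reference Named character vector; defaults to the union
#'   of the pair's chromosomes. Chromosome name prefix (`O`/`R`) defines the
#'   subgenome.
#' @param read_length Read length in bp (>= k).
#' @param n_reads Reads sampled per parent.
#' @param k K-mer size (default 31).
#' @param seed Integer RNG seed.
#' @return Data frame per parent: `parent`, `n_reads`, `correct`, `wrong`,
#'   `unassigned`, `correct_fraction` (correct / n_reads).
#' @export
validate_assignment_by_simulation <- function(pair, combined_reference = NULL,
                                              read_length = 150L,
                                              n_reads = 1000L, k = 31L,
                                              seed = 1L) {
  if (read_length < 31L) stop("read_length must be >= 31")
  if (k > read_length) stop("k larger than read_length")
  ref <- combined_reference %||% c(pair$genomeO, pair$genomeR)

  # diagnostic k-mer table: k-mer -> chromosome (multi-chromosome k-mers
  # are dropped as non-diagnostic)
  kmer_sets <- lapply(ref, function(seq) {
    n <- nchar(seq)
    unique(substring(seq, 1:(n - k + 1L), k:n))
  })
  all_kmers <- unlist(kmer_sets, use.names = FALSE)
  chrom_of <- rep(names(kmer_sets), lengths(kmer_sets))
  dup <- all_kmers %in% all_kmers[duplicated(all_kmers)]
  tab_kmers <- all_kmers[!dup]
  tab_chrom <- chrom_of[!dup]

  with_seed_or_not(seed, {
    res <- lapply(c(O = "genomeO", R = "genomeR"), function(gslot) {
      genome <- pair[[gslot]]
      lens <- nchar(genome)
      chrom <- sample(names(genome), n_reads, replace = TRUE, prob = lens)
      start <- floor(runif(n_reads) * (lens[chrom] - read_length)) + 1L
      reads <- substr(genome[chrom], start, start + read_length - 1L)
      nk <- read_length - k + 1L
      # all k-mers of all reads, matched against the table in one call
      km <- vapply(seq_len(nk), function(i) substr(reads, i, i + k - 1L),
                   character(n_reads))
      hits <- matrix(match(as.vector(km), tab_kmers), n_reads, nk)
      assigned <- apply(hits, 1L, function(h) {
        h <- h[!is.na(h)]
        if (length(h) == 0L) return(NA_character_)
        votes <- table(tab_chrom[h])
        top <- votes[votes == max(votes)]
        if (length(top) > 1L) NA_character_ else names(top)
      })
      sub <- substr(assigned, 1L, 1L)
      parent <- substr(gslot, 7L, 7L)
      data.frame(parent = parent, n_reads = n_reads,
                 correct = sum(sub == parent, na.rm = TRUE),
                 wrong = sum(sub != parent, na.rm = TRUE),
                 unassigned = sum(is.na(sub)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$correct_fraction <- out$correct / out$n_reads
    rownames(out) <- NULL
    out
  })
}
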