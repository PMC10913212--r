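#' Check whether a CDS is a valid open reading frame
#'
#' Valid means: length at least 6 and divisible by 3, starts with `ATG`,
#' ends with a stop codon (`TAA`/`TAG`/`TGA`) and has no internal in-frame
#' stop. Sequences containing characters outside `A,C,G,T,N` are rejected
#' with an error.
#'
#' @param cds Nucleotide sequence (character scalar).
#' @return `TRUE` or `FALSE`.
#' @export
validate_orf <- function(cds) {
  if (grepl("[^ACGTN]", cds)) stop("non-nucleotide characters in CDS")
  n <- nchar(cds)
  if (n < 6L || n %% 3L != 0L) return(FALSE)
  if (substr(cds, 1L, 3L) != "ATG") return(FALSE)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  stops <- c("TAA", "TAG", "TGA")
  if (!(codons[length(codons)] %in% stops)) return(FALSE)
  !any(codons[-length(codons)] %in% stops)
}

#' K-mer seeded ungapped similarity search between CDS sets
#'
#' For each query, finds subjects sharing at least one exact k-mer. Every
#' shared k-mer defines an alignment diagonal; each candidate diagonal is
#' scored by the maximum-scoring ungapped segment (match +1, mismatch -1)
#' and the best diagonal per query/subject pair is kept. Identity is the
#' match fraction within that segment.
#'
#' @param queries,subjects Named character vectors of nucleotide sequences.
#' @param k Seed length (default 11).
#' @return Data frame `query`, `subject`, `score`, `identity`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `seg_length`, sorted by query then
#'   decreasing score. Zero rows when nothing shares a k-mer.
#' @export
similarity_search <- function(queries, subjects, k = 11L) {
  stopifnot(length(queries) > 0L, length(subjects) > 0L,
            !is.null(names(queries)), !is.null(names(subjects)))
  s_chars <- lapply(subjects, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  q_chars <- lapply(queries, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  # subject k-mer index: kmer -> integer code subject_index * 1e9 + position
  pool_kmer <- character(0); pool_subj <- integer(0); pool_pos <- integer(0)
  for (si in seq_along(subjects)) {
    n <- nchar(subjects[[si]])
    if (n < k) next
    km <- substring(subjects[[si]], 1:(n - k + 1L), k:n)
    pool_kmer <- c(pool_kmer, km)
    pool_subj <- c(pool_subj, rep(si, length(km)))
    pool_pos <- c(pool_pos, seq_along(km))
  }
  index <- split(seq_along(pool_kmer), pool_kmer)

  hits <- list()
  for (qi in seq_along(queries)) {
    qn <- nchar(queries[[qi]])
    if (qn < k) next
    qkm <- substring(queries[[qi]], 1:(qn - k + 1L), k:qn)
    found <- index[unique(qkm[qkm %in% names(index)])]
    if (length(found) == 0L) next
    cand <- data.frame(
      qpos = rep(match(names(found), qkm), lengths(found)),
      entry = unlist(found, use.names = FALSE))
    # NOTE: match() gives the first query occurrence of each k-mer; repeated
    # query k-mers add no new diagonals at the divergence levels targeted.
    cand$subj <- pool_subj[cand$entry]
    cand$diag <- cand$qpos - pool_pos[cand$entry]
    cand <- unique(cand[, c("subj", "diag")])
    best <- list()
    for (r in seq_len(nrow(cand))) {
      si <- cand$subj[r]; d <- cand$diag[r]
      sn <- length(s_chars[[si]])
      i0 <- max(1L, d + 1L); i1 <- min(qn, sn + d)
      if (i1 - i0 + 1L < k) next
      v <- ifelse(q_chars[[qi]][i0:i1] == s_chars[[si]][(i0:i1) - d], 1L, -1L)
      seg <- max_subarray(v)
      if (seg$score <= 0L) next
      qs <- i0 + seg$start - 1L; qe <- i0 + seg$end - 1L
      rec <- data.frame(
        query = names(queries)[qi], subject = names(subjects)[si],
        score = seg$score,
        identity = seg$matches / seg$length,
        q_start = qs, q_end = qe, s_start = qs - d, s_end = qe - d,
        seg_length = seg$length, stringsAsFactors = FALSE)
      key <- as.character(si)
      if (is.null(best[[key]]) || rec$score > best[[key]]$score)
        best[[key]] <- rec
    }
    hits <- c(hits, best)
  }
  if (length(hits) == 0L)
    return(data.frame(query = character(0), subject = character(0),
                      score = integer(0), identity = numeric(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      seg_length = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$query, -out$score, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximum-scoring contiguous segment of a +1/-1 vector (Kadane), with the
# segment bounds and match count.
max_subarray <- function(v) {
  best <- 0L; cur <- 0L; cur_start <- 1L
  bs <- 0L; be <- -1L
  for (i in seq_along(v)) {
    cur <- cur + v[i]
    if (cur <= 0L) { cur <- 0L; cur_start <- i + 1L }
    else if (cur > best) { best <- cur; bs <- cur_start; be <- i }
  }
  if (be < bs) return(list(score = 0L, start = 0L, end = -1L,
                           matches = 0L, length = 0L))
  seg <- v[bs:be]
  list(score = best, start = bs, end = be,
       matches = sum(seg == 1L), length = length(seg))
}

#' Extract CDS sequences for gene models from a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param annot Data frame with `id`, `chromosome`, `start`, `end`, `strand`.
#' @return Named character vector of CDS (minus-strand genes are
#'   reverse-complemented).
#' @export
extract_cds <- function(genome, annot) {
  seqs <- substr(genome[annot$chromosome], annot$start, annot$end)
  minus <- annot$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  stats::setNames(seqs, annot$id)
}

# ordinal rank of every gene along its chromosome (by start)
gene_ranks <- function(annot) {
  rk <- integer(nrow(annot))
  for (chrom in unique(annot$chromosome)) {
    i <- which(annot$chromosome == chrom)
    rk[i] <- rank(annot$start[i], ties.method = "first")
  }
  stats::setNames(rk, annot$id)
}

#' Pair homeologous genes between the R and O subgenomes
#'
#' Reciprocal best hits are paired first. When a query has several equally
#' scoring hits, the candidate whose ordinal position along its chromosome
#' best matches the query's position wins (minimum |rank difference|, then
#' lexicographic subject id). Remaining one-directional best hits are
#' accepted - best score first - when their rank distance is at most
#' `max_rank_distance` and both genes are still unpaired. Every gene appears
#' in at most one pair; the procedure is symmetric in R and O.
#'
#' @param hits_r_to_o Hits of R-subgenome CDS against O-subgenome CDS
#'   ([similarity_search()] output or an equivalent table with `query`,
#'   `subject`, `score` columns).
#' @param hits_o_to_r The reverse search.
#' @param annot_r,annot_o Gene model tables (`id`, `chromosome`, `start`,
#'   `end`, `strand`), each sorted by `start` within chromosome.
#' @param max_rank_distance Rank-distance cutoff for non-reciprocal pairs
#'   (default 10).
#' @return Data frame `geneR`, `geneO`, `method` (`"primary"` for
#'   reciprocal best hits, `"best_hit"` otherwise), `score`.
#' @export
pair_homeologs <- function(hits_r_to_o, hits_o_to_r, annot_r, annot_o,
                           max_rank_distance = 10L) {
  known <- c(annot_r$id, annot_o$id)
  bad <- setdiff(unique(c(hits_r_to_o$query, hits_r_to_o$subject,
                          hits_o_to_r$query, hits_o_to_r$subject)), known)
  if (length(bad))
    stop("hits reference unknown gene ids: ", paste(head(bad, 3), collapse = ", "))
  rank_r <- gene_ranks(annot_r); rank_o <- gene_ranks(annot_o)
  ranks <- c(rank_r, rank_o)

  best_of <- function(hits) {
    out <- lapply(split(hits, hits$query), function(h) {
      h <- h[h$score == max(h$score), , drop = FALSE]
      rd <- abs(ranks[h$query] - ranks[h$subject])
      h <- h[order(rd, h$subject), , drop = FALSE]
      h[1L, c("query", "subject", "score")]
    })
    do.call(rbind, out)
  }
  bestR <- best_of(hits_r_to_o)  # query = R gene
  bestO <- best_of(hits_o_to_r)  # query = O gene

  to_o <- stats::setNames(bestR$subject, bestR$query)
  to_r <- stats::setNames(bestO$subject, bestO$query)

  recip <- bestR$query[!is.na(to_r[to_o[bestR$query]]) &
                         to_r[to_o[bestR$query]] == bestR$query]
  pairs <- data.frame(geneR = recip, geneO = unname(to_o[recip]),
                      method = "primary",
                      score = bestR$score[match(recip, bestR$query)],
                      stringsAsFactors = FALSE)

  # one-directional leftovers, best score first, rank distance bounded
  lo_r <- bestR[!(bestR$query %in% pairs$geneR) &
                  !(bestR$subject %in% pairs$geneO), , drop = FALSE]
  lo_o <- bestO[!(bestO$query %in% pairs$geneO) &
                  !(bestO$subject %in% pairs$geneR), , drop = FALSE]
  cand <- rbind(
    if (nrow(lo_r)) data.frame(geneR = lo_r$query, geneO = lo_r$subject,
                               score = lo_r$score, stringsAsFactors = FALSE),
    if (nrow(lo_o)) data.frame(geneR = lo_o$subject, geneO = lo_o$query,
                               score = lo_o$score, stringsAsFactors = FALSE))
  if (!is.null(cand) && nrow(cand)) {
    cand$rd <- abs(ranks[cand$geneR] - ranks[cand$geneO])
    cand <- cand[cand$rd <= max_rank_distance, , drop = FALSE]
    cand <- cand[order(-cand$score, cand$geneR, cand$geneO), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      if (!(cand$geneR[i] %in% pairs$geneR) &&
          !(cand$geneO[i] %in% pairs$geneO)) {
        pairs <- rbind(pairs, data.frame(
          geneR = cand$geneR[i], geneO = cand$geneO[i],
          method = "best_hit", score = cand$score[i],
          stringsAsFactors = FALSE))
      }
    }
  }
  pairs <- pairs[order(pairs$geneR), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Rescue unpaired genes by interval-constrained similarity search
#'
#' For each annotated gene left without a homeolog, the interval of the
#' other subgenome bounded by the partners of its nearest paired neighbours
#' (or the chromosome end, when the gene sits at an end) is scanned with the
#' gene's CDS. A hit with identity at least `min_identity` whose projected
#' region carries a valid ORF and overlaps no existing gene becomes a new
#' gene model and a rescue pair. Genes whose flanking partners disagree on
#' the chromosome are skipped (inconsistent synteny); genes without a
#' qualifying hit are reported as genuinely missing.
#'
#' @param pairs Pair table from [pair_homeologs()].
#' @param annot_r,annot_o Gene model tables.
#' @param genome_r,genome_o Named character vectors of chromosome sequences.
#' @param k Seed length for the interval scan.
#' @param min_identity Identity cutoff (default 0.8).
#' @param min_coverage Minimum fraction of the query covered by the matched
#'   segment (default 0.5).
#' @param margin Bp added on both sides of the search interval.
#' @return List with `pairs` (new rows, `method = "rescue"`), `new_models`
#'   (gene model rows for the rescued partners) and `missing` (data frame
#'   `gene`, `reason`).
#' @export
rescue_missing <- function(pairs, annot_r, annot_o, genome_r, genome_o,
                           k = 11L, min_identity = 0.8, min_coverage = 0.5,
                           margin = 50L) {
  res_pairs <- list(); new_models <- list(); missing <- list()

  rescue_side <- function(annot_q, annot_s, genome_s, q_is_r) {
    cds_q <- extract_cds(if (q_is_r) genome_r else genome_o, annot_q)
    paired_q <- if (q_is_r) pairs$geneR else pairs$geneO
    partner_of <- if (q_is_r)
      stats::setNames(pairs$geneO, pairs$geneR) else
      stats::setNames(pairs$geneR, pairs$geneO)
    for (gi in which(!(annot_q$id %in% paired_q))) {
      g <- annot_q[gi, ]
      sib <- annot_q[annot_q$chromosome == g$chromosome &
                       annot_q$id %in% paired_q, , drop = FALSE]
      left <- sib[sib$start < g$start, , drop = FALSE]
      right <- sib[sib$start > g$start, , drop = FALSE]
      lp <- if (nrow(left)) partner_of[[left$id[which.max(left$start)]]] else NA
      rp <- if (nrow(right)) partner_of[[right$id[which.min(right$start)]]] else NA
      if (is.na(lp) && is.na(rp)) {
        missing[[length(missing) + 1L]] <<- data.frame(
          gene = g$id, reason = "no_paired_flank", stringsAsFactors = FALSE)
        next
      }
      lpm <- if (!is.na(lp)) annot_s[annot_s$id == lp, ] else NULL
      rpm <- if (!is.na(rp)) annot_s[annot_s$id == rp, ] else NULL
      s_chrom <- unique(c(lpm$chromosome, rpm$chromosome))
      if (length(s_chrom) != 1L) {
        missing[[length(missing) + 1L]] <<- data.frame(
          gene = g$id, reason = "inconsistent_synteny", stringsAsFactors = FALSE)
        next
      }
      L <- nchar(genome_s[[s_chrom]])
      lo <- max(1L, (if (is.null(lpm)) 1L else lpm$end + 1L) - margin)
      hi <- min(L, (if (is.null(rpm)) L else rpm$start - 1L) + margin)
      if (hi - lo + 1L < k) {
        missing[[length(missing) + 1L]] <<- data.frame(
          gene = g$id, reason = "no_hit", stringsAsFactors = FALSE)
        next
      }
      interval <- substr(genome_s[[s_chrom]], lo, hi)
      q <- cds_q[g$id]
      hit_f <- similarity_search(q, c(ivl = interval), k = k)
      hit_r <- similarity_search(q, c(ivl = revcomp(interval)), k = k)
      use_rev <- (nrow(hit_r) && !nrow(hit_f)) ||
        (nrow(hit_r) && nrow(hit_f) && hit_r$score[1] > hit_f$score[1])
      hit <- if (use_rev) hit_r else hit_f
      qlen <- nchar(q)
      if (nrow(hit) == 0L || hit$identity[1] < min_identity ||
          hit$seg_length[1] < min_coverage * qlen) {
        missing[[length(missing) + 1L]] <<- data.frame(
          gene = g$id, reason = "no_hit", stringsAsFactors = FALSE)
        next
      }
      h <- hit[1L, ]
      # project the full query onto the interval
      m <- nchar(interval)
      s_lo <- max(1L, h$s_start - (h$q_start - 1L))
      s_hi <- min(m, h$s_end + (qlen - h$q_end))
      if (use_rev) { tmp <- s_lo; s_lo <- m - s_hi + 1L; s_hi <- m - tmp + 1L }
      abs_start <- lo + s_lo - 1L; abs_end <- lo + s_hi - 1L
      # cds_q is already strand-corrected, so the new model is minus-strand
      # exactly when the reverse-complemented interval matched
      strand <- if (use_rev) "-" else "+"
      region <- substr(genome_s[[s_chrom]], abs_start, abs_end)
      cds_new <- if (strand == "-") revcomp(region) else region
      if (!validate_orf(cds_new)) {
        missing[[length(missing) + 1L]] <<- data.frame(
          gene = g$id, reason = "invalid_orf", stringsAsFactors = FALSE)
        next
      }
      overlap <- annot_s$chromosome == s_chrom &
        annot_s$start <= abs_end & annot_s$end >= abs_start
      if (any(overlap)) {
        missing[[length(missing) + 1L]] <<- data.frame(
          gene = g$id, reason = "overlaps_existing", stringsAsFactors = FALSE)
        next
      }
      new_id <- paste0(g$id, "_h")
      new_models[[length(new_models) + 1L]] <<- data.frame(
        id = new_id, chromosome = s_chrom, start = abs_start, end = abs_end,
        strand = strand, stringsAsFactors = FALSE)
      res_pairs[[length(res_pairs) + 1L]] <<- data.frame(
        geneR = if (q_is_r) g$id else new_id,
        geneO = if (q_is_r) new_id else g$id,
        method = "rescue", score = h$score, stringsAsFactors = FALSE)
    }
  }

  rescue_side(annot_r, annot_o, genome_o, q_is_r = TRUE)
  rescue_side(annot_o, annot_r, genome_r, q_is_r = FALSE)

  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(pairs = bind(res_pairs,
                    data.frame(geneR = character(0), geneO = character(0),
                               method = character(0), score = integer(0))),
       new_models = bind(new_models,
                         data.frame(id = character(0), chromosome = character(0),
                                    start = integer(0), end = integer(0),
                                    strand = character(0))),
       missing = bind(missing,
                      data.frame(gene = character(0), reason = character(0))))
}

#' Assign systematic gene names
#'
#' The i-th gene along a chromosome is numbered `i * 1000` (zero-padded to 8
#' digits; the spacing leaves room for genes discovered later) and named
#' `Cbp.<chromosome>.g<number>.<A. thaliana ortholog>_<method letter>`,
#' e.g. `Cbp.O1.g00001000.AT1G02140_O`. The method letter records how the
#' *A. thaliana* correspondence was found: `O` orthogroup, `B` best
#' similarity hit. Genes without a correspondence get `NA` in the ortholog
#' slot.
#'
#' @param annot Gene model table sorted by `start` within each chromosome.
#' @param at_orthologs Optional data frame `gene`, `at_id`, `method`
#'   (letters `"O"`/`"B"`). Genes absent from it get `NA_B`.
#' @return Named character vector: gene id -> systematic name.
#' @export
name_genes <- function(annot, at_orthologs = NULL) {
  for (chrom in unique(annot$chromosome)) {
    s <- annot$start[annot$chromosome == chrom]
    if (is.unsorted(s, strictly = TRUE))
      stop("annotation must be sorted by start within chromosome: ", chrom)
  }
  at <- rep("NA", nrow(annot)); letter <- rep("B", nrow(annot))
  if (!is.null(at_orthologs)) {
    m <- match(annot$id, at_orthologs$gene)
    at[!is.na(m)] <- at_orthologs$at_id[m[!is.na(m)]]
    letter[!is.na(m)] <- at_orthologs$method[m[!is.na(m)]]
  }
  idx <- stats::ave(seq_len(nrow(annot)), annot$chromosome,
                    FUN = seq_along)
  names_out <- sprintf("Cbp.%s.g%08d.%s_%s", annot$chromosome, idx * 1000L,
                       at, letter)
  if (anyDuplicated(names_out)) stop("duplicate gene names generated")
  stats::setNames(names_out, annot$id)
}

#' Parse a systematic gene name back into its components
#'
#' @param name Character vector of names produced by [name_genes()].
#' @return Data frame `prefix`, `chromosome`, `number`, `at_id`, `method`.
#' @export
parse_gene_name <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed gene name: ", name[bad][1])
  df <- do.call(rbind, lapply(parts, function(p) {
    last <- p[4]
    us <- regexpr("_[^_]*$", last)
    data.frame(prefix = p[1], chromosome = p[2],
               number = as.integer(sub("^g", "", p[3])),
               at_id = substr(last, 1L, us - 1L),
               method = substr(last, us + 1L, nchar(last)),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
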