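#' Build the homozygous SNP marker database from F0 parent variants
#'
#' Retains biallelic SNP records at which the second F0 parent is homozygous
#' for the non-reference allele; these positions segregate 1:2:1 in the F2
#' and are the markers of the genetic map. Multi-allelic records and indels
#' are skipped (counts reported via message).
#'
#' @param f0_variants Data frame of F0 variant records with columns
#'   `contig`, `position`, `ref`, `alt`, `gt` (e.g. `"1/1"`), `dp`; extra
#'   columns (e.g. `source_chrom`, `source_pos`) are carried through.
#'   Alternatively a path to a VCF file (read via \pkg{vcfR}).
#' @return A `marker_db` data frame sorted by (contig, position).
#' @export
build_marker_db <- function(f0_variants) {
  if (is.character(f0_variants) && length(f0_variants) == 1L)
    f0_variants <- read_vcf_records(f0_variants)
  v <- f0_variants
  is_snp <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    !grepl(",", v$alt, fixed = TRUE) &
    v$ref %in% DNA_BASES & v$alt %in% DNA_BASES
  hom_alt <- v$gt %in% c("1/1", "1|1")
  n_skip_snp <- sum(!is_snp)
  n_skip_het <- sum(is_snp & !hom_alt)
  if (n_skip_snp + n_skip_het > 0L)
    message("build_marker_db: skipped ", n_skip_snp,
            " non-SNP and ", n_skip_het, " non-hom-alt records")
  db <- v[is_snp & hom_alt, , drop = FALSE]
  if (nrow(db) == 0L) warning("empty marker database")
  db <- db[order(db$contig, db$position), , drop = FALSE]
  if (anyDuplicated(db[, c("contig", "position")]))
    stop("duplicate marker positions within a contig")
  rownames(db) <- NULL
  class(db) <- c("marker_db", "data.frame")
  db
}

#' Call per-plant marker states from genotype and depth evidence
#'
#' For every marker of the database and every F2 plant, assigns the
#' four-state code used for map construction: `-1` homozygous reference,
#' `0` heterozygous, `1` homozygous for the parent-2 allele, `NA` when the
#' evidence is insufficient (depth below `min_depth` or no call).
#'
#' @param db A `marker_db`.
#' @param cohort Either an `f2_cohort` (markers matched through the db's
#'   `source_chrom`/`source_pos` columns, or by `contig:position` row name)
#'   or a named list of per-plant call data frames with columns `contig`,
#'   `position`, `gt`, `dp`.
#' @param depths Optional markers x plants depth matrix for the list input
#'   (rows keyed `contig:position`); sites absent from a plant's calls but
#'   covered at `>= min_depth` are called homozygous reference.
#' @param min_depth Minimum depth to emit a call (default 2).
#' @return A `marker_state_table`: list with `states` (markers x plants
#'   integer matrix over \{-1, 0, 1, NA\}), `markers` (data frame `contig`,
#'   `position`) and `plants`.
#' @export
call_marker_states <- function(db, cohort, depths = NULL, min_depth = 2L) {
  if (nrow(db) == 0L) stop("marker database is empty")
  markers <- data.frame(contig = db$contig, position = db$position,
                        stringsAsFactors = FALSE)
  rn <- paste0(db$contig, ":", db$position)

  if (inherits(cohort, "f2_cohort")) {
    key <- if (!is.null(db$source_chrom))
      paste0(db$source_chrom, ":", db$source_pos) else rn
    idx <- match(key, rownames(cohort$markers))
    if (anyNA(idx)) stop("db markers missing from cohort")
    states <- cohort$called[idx, , drop = FALSE] - 1L
    states[cohort$depths[idx, , drop = FALSE] < min_depth] <- NA_integer_
    rownames(states) <- rn
  } else {
    plants <- names(cohort)
    states <- matrix(NA_integer_, nrow(db), length(plants),
                     dimnames = list(rn, plants))
    code <- c("0/0" = -1L, "0|0" = -1L, "0/1" = 0L, "0|1" = 0L,
              "1|0" = 0L, "1/1" = 1L, "1|1" = 1L)
    for (p in plants) {
      calls <- cohort[[p]]
      if (is.null(calls) || nrow(calls) == 0L) {
        message("plant ", p, " has no calls: all markers missing")
        next
      }
      m <- match(rn, paste0(calls$contig, ":", calls$position))
      st <- unname(code[calls$gt[m]])
      dp <- calls$dp[m]
      st[!is.na(dp) & dp < min_depth] <- NA_integer_
      if (!is.null(depths) && p %in% colnames(depths)) {
        d <- depths[rn, p]
        st[is.na(m) & d >= min_depth] <- -1L  # covered, no variant call
      }
      states[, p] <- st
    }
  }
  structure(list(states = states, markers = markers,
                 plants = colnames(states)),
            class = "marker_state_table")
}

#' Chi-square critical value for the 1:2:1 segregation filter
#'
#' @param alpha Significance level (default 0.05).
#' @param df Degrees of freedom (default 2, for the three genotype classes).
#' @return The upper-tail critical value of the chi-square distribution.
#' @export
segregation_chi2_threshold <- function(alpha = 0.05, df = 2) {
  qchisq(1 - alpha, df)
}

#' Filter markers by missingness and 1:2:1 segregation
#'
#' Removes markers unidentified in more than `max_missing_fraction` of the
#' plants, then markers whose homozygote/heterozygote counts depart from the
#' Mendelian 1:2:1 expectation by Pearson's criterion: with observed counts
#' (n(-1), n(0), n(1)) over n informative plants and expected counts
#' n(1/4, 1/2, 1/4), markers with chi-square above `chi2_threshold`
#' (default 5.99, the 5% critical value at 2 df) are dropped.
#'
#' @param table A `marker_state_table`.
#' @param max_missing_fraction Maximum tolerated missing fraction (strict
#'   `>` removes; default 0.5).
#' @param chi2_threshold Pearson criterion threshold (default
#'   [segregation_chi2_threshold()], i.e. 5.99).
#' @return List with `table` (filtered `marker_state_table`) and `log`
#'   (data frame `marker`, `reason`, `value`).
#' @export
filter_markers <- function(table, max_missing_fraction = 0.5,
                           chi2_threshold = segregation_chi2_threshold()) {
  st <- table$states
  if (nrow(st) == 0L) stop("marker state table is empty")
  miss_frac <- rowMeans(is.na(st))
  chi2 <- apply(st, 1L, marker_chi2)
  drop_miss <- miss_frac > max_missing_fraction
  drop_seg <- !drop_miss & !is.na(chi2) & chi2 > chi2_threshold
  log <- rbind(
    data.frame(marker = rownames(st)[drop_miss],
               reason = rep("missingness", sum(drop_miss)),
               value = miss_frac[drop_miss], stringsAsFactors = FALSE),
    data.frame(marker = rownames(st)[drop_seg],
               reason = rep("segregation", sum(drop_seg)),
               value = chi2[drop_seg], stringsAsFactors = FALSE))
  keep <- !(drop_miss | drop_seg)
  if (!any(keep)) stop("all markers removed: no map can be built")
  out <- table
  out$states <- st[keep, , drop = FALSE]
  out$markers <- table$markers[keep, , drop = FALSE]
  rownames(log) <- NULL
  list(table = out, log = log)
}

# Pearson chi-square of a state vector against 1:2:1 (NA if no data).
marker_chi2 <- function(states) {
  obs <- c(sum(states == -1L, na.rm = TRUE), sum(states == 0L, na.rm = TRUE),
           sum(states == 1L, na.rm = TRUE))
  n <- sum(obs)
  if (n == 0L) return(NA_real_)
  expd <- n * c(0.25, 0.5, 0.25)
  sum((obs - expd)^2 / expd)
}

#' Count recombination events between two marker state vectors
#'
#' Over the plants where both markers are informative, each unit change of
#' genotype counts one event per homologous chromosome: the event count is
#' the sum of |g1 - g2| with g in \{-1, 0, 1\} (a -1 to 1 change counts two
#' events). The rate is expressed per 100 chromosomes, 2 chromosomes per
#' informative plant. For truly unlinked markers the expected rate is 37.5
#' per 100 - far above anything physical linkage can produce - which is the
#' misassembly signature.
#'
#' @param states_m1,states_m2 Integer state vectors over \{-1, 0, 1, NA\}.
#' @return List with `events`, `informative` (plant count) and
#'   `rate_per_100` (NA when no plant is informative).
#' @export
count_interval_recombinations <- function(states_m1, states_m2) {
  stopifnot(length(states_m1) == length(states_m2))
  ok <- !is.na(states_m1) & !is.na(states_m2)
  events <- sum(abs(states_m1[ok] - states_m2[ok]))
  informative <- sum(ok)
  rate <- if (informative == 0L) NA_real_ else 100 * events / (2 * informative)
  list(events = events, informative = informative, rate_per_100 = rate)
}

#' Detect misassembled contigs from excess recombination
#'
#' Scans adjacent marker pairs within each contig: physically adjacent
#' markers are tightly linked, so more than `max_recombinations` observed
#' events between them indicates that the two markers are in fact inherited
#' independently, i.e. the contig chimerically joins unlinked sequence. Each
#' such interval is reported as a candidate split point.
#'
#' @param table A `marker_state_table` (markers ordered by position within
#'   contig, as produced by [call_marker_states()]).
#' @param max_recombinations Events tolerated between adjacent markers
#'   (default 2; flagging is strict `>`).
#' @return Data frame `contig`, `start`, `end` (positions of the flanking
#'   markers), `events`, `informative`, `rate_per_100`. Contigs with fewer
#'   than two markers are skipped and listed in attribute `"skipped"`.
#' @export
detect_misassemblies <- function(table, max_recombinations = 2L) {
  st <- table$states
  mk <- table$markers
  out <- list(); skipped <- character(0)
  for (ctg in unique(mk$contig)) {
    rows <- which(mk$contig == ctg)
    rows <- rows[order(mk$position[rows])]
    if (length(rows) < 2L) { skipped <- c(skipped, ctg); next }
    for (j in seq_len(length(rows) - 1L)) {
      r <- count_interval_recombinations(st[rows[j], ], st[rows[j + 1L], ])
      if (r$events > max_recombinations) {
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg,
          start = mk$position[rows[j]], end = mk$position[rows[j + 1L]],
          events = r$events, informative = r$informative,
          rate_per_100 = r$rate_per_100, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               events = integer(0), informative = integer(0),
               rate_per_100 = numeric(0), stringsAsFactors = FALSE)
  if (length(skipped))
    message("detect_misassemblies: skipped ", length(skipped),
            " contig(s) with < 2 markers")
  attr(res, "skipped") <- skipped
  res
}

#' Drop markers implicated in recurrent high-recombination intervals
#'
#' Automates the removal of locally noisy map regions: any marker bounding
#' two or more flagged intervals is removed from the state table.
#'
#' @param table A `marker_state_table`.
#' @param flagged Data frame from [detect_misassemblies()].
#' @return The filtered `marker_state_table`.
#' @export
filter_hot_markers <- function(table, flagged) {
  if (nrow(flagged) == 0L) return(table)
  ids <- c(paste0(flagged$contig, ":", flagged$start),
           paste0(flagged$contig, ":", flagged$end))
  hot <- names(which(table(ids) >= 2L))
  keep <- !(rownames(table$states) %in% hot)
  table$states <- table$states[keep, , drop = FALSE]
  table$markers <- table$markers[keep, , drop = FALSE]
  table
}

#' Code contigs as map markers from per-contig mean states
#'
#' For every contig and plant, averages the non-missing marker states and
#' maps the mean onto the four-letter contig code used for linkage grouping:
#' `A` (mean in [-1, -0.8], homozygous reference), `B` ([0.8, 1]), `X`
#' ([-0.2, 0.2], heterozygous); means in the intermediate intervals - the
#' signature of a crossover inside the contig - are undefined (`NA`), as is
#' an all-missing contig/plant combination.
#'
#' @param table A `marker_state_table`.
#' @return A `contig_code_table`: list with `codes` (contigs x plants
#'   character matrix over \{"A","B","X",NA\}) and `means` (numeric matrix).
#' @export
code_contigs <- function(table) {
  st <- table$states
  groups <- split(seq_len(nrow(st)), table$markers$contig)
  means <- do.call(rbind, lapply(groups, function(rows) {
    colMeans(st[rows, , drop = FALSE], na.rm = TRUE)
  }))
  means[is.nan(means)] <- NA_real_
  codes <- matrix(NA_character_, nrow(means), ncol(means),
                  dimnames = dimnames(means))
  codes[!is.na(means) & means <= -0.8] <- "A"
  codes[!is.na(means) & means >= 0.8] <- "B"
  codes[!is.na(means) & abs(means) <= 0.2] <- "X"
  structure(list(codes = codes, means = means),
            class = "contig_code_table")
}
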