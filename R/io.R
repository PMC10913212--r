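#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a depth track as 4-column bedGraph-style TSV
#'
#' Columns: chromosome, 0-based window start, window end, depth.
#'
#' @param track A `depth_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    L <- track$chrom_lengths[[chrom]]
    starts <- (seq_along(v) - 1L) * track$window_size
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + track$window_size, L), depth = v)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph-style depth TSV into a depth track
#'
#' @param path Input file (chrom, 0-based start, end, depth).
#' @param sample Sample label to attach.
#' @return A `depth_track`.
#' @export
read_depth_bedgraph <- function(path, sample = NA_character_) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "depth"),
                   stringsAsFactors = FALSE)
  window_size <- max(df$end - df$start)
  values <- lapply(split(df, df$chrom), function(d) d$depth[order(d$start)])
  lens <- vapply(split(df$end, df$chrom), max, numeric(1))
  structure(list(sample = sample, window_size = window_size,
                 values = values, chrom_lengths = lens),
            class = "depth_track")
}

#' Write Hi-C contact pairs as 4-column TSV
#'
#' @param pairs Data frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hic_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read Hi-C contact pairs from 4-column TSV
#'
#' @param path Input file.
#' @return Data frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
read_hic_pairs <- function(path) {
  read.table(path, sep = "\t", header = FALSE,
             col.names = c("chrom1", "pos1", "chrom2", "pos2"),
             stringsAsFactors = FALSE)
}

#' Write an F2 cohort as a multi-sample VCF (GT and DP)
#'
#' @param cohort An `f2_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_f2_vcf <- function(cohort, path) {
  mk <- cohort$markers
  gt_str <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(cohort$called)),
                     collapse = "\t")), con)
  for (i in seq_len(nrow(mk))) {
    g <- cohort$called[i, ]
    cells <- ifelse(is.na(g), paste0("./.:", cohort$depths[i, ]),
                    paste0(gt_str[g + 1L], ":", cohort$depths[i, ]))
    writeLines(paste(c(mk$chromosome[i], mk$position[i], ".",
                       mk$ref[i], mk$alt[i], ".", "PASS", ".", "GT:DP",
                       cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read VCF records into a flat per-sample table
#'
#' Uses \pkg{vcfR}; multi-sample files yield one row per sample and site.
#'
#' @param path VCF file.
#' @return Data frame `contig`, `position`, `ref`, `alt`, `sample`, `gt`,
#'   `dp` (also aliased as `chrom`/`pos` columns).
#' @export
read_vcf_records <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  out <- do.call(rbind, lapply(colnames(gt), function(s) {
    data.frame(contig = fix$CHROM, position = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT, sample = s,
               gt = gt[, s], dp = dp[, s], stringsAsFactors = FALSE)
  }))
  out$chrom <- out$contig
  out$pos <- out$position
  rownames(out) <- NULL
  out
}

#' Write a marker state table as TSV
#'
#' @param table A `marker_state_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_marker_states <- function(table, path) {
  df <- data.frame(contig = table$markers$contig,
                   position = table$markers$position,
                   table$states, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pseudoalignment as multi-FASTA
#'
#' @param aln A `pseudoalignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pseudoalignment <- function(aln, path) {
  x <- Biostrings::BStringSet(aln$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
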