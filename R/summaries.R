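#' Bookkeeping summary of a subgenome-aware gene annotation
#'
#' Aggregates per-subgenome chromosome-located gene counts against the
#' total annotated set: the chromosome-located total and the percentage of
#' all genes placed on chromosome scaffolds (one decimal, the figure
#' usually quoted for assembly completeness at the gene level).
#'
#' @param per_subgenome Named numeric vector of chromosome-located gene
#'   counts per subgenome (e.g. `c(O = ..., R = ...)`).
#' @param total_annotated Total number of annotated genes.
#' @return List with `chromosome_located`, `total_annotated`,
#'   `percent_located` (rounded to one decimal).
#' @export
gene_count_summary <- function(per_subgenome, total_annotated) {
  stopifnot(all(per_subgenome >= 0), total_annotated > 0)
  located <- sum(per_subgenome)
  if (located > total_annotated)
    stop("located genes exceed the annotated total")
  list(chromosome_located = located,
       total_annotated = total_annotated,
       percent_located = round(100 * located / total_annotated, 1))
}
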