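test_that("ORF validation follows the start/stop/frame rules", {
  expect_true(validate_orf("ATGAAATGA"))
  expect_true(validate_orf("ATGTGA"))
  expect_false(validate_orf("ATGTAAAAATGA"))  # internal in-frame stop
  expect_false(validate_orf("ATGAAA"))        # no stop
  expect_false(validate_orf("ATGAAATG"))      # length not divisible by 3
  expect_false(validate_orf("TTGAAATGA"))     # no ATG start
  expect_error(validate_orf("ATGXAATGA"), "non-nucleotide")
})

test_that("similarity search finds true partners and ignores noise", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  hits <- similarity_search(c(q = s), c(s = s))
  expect_equal(hits$identity[1], 1)
  expect_equal(hits$score[1], 600)

  # 1% diverged homeolog pair: best hit is the true partner
  gm <- simulate_gene_models(100000, 10, 900, 0.01, seed = 6)
  cdsO <- extract_cds(gm$genomeO, gm$annotO)
  cdsR <- extract_cds(gm$genomeR, gm$annotR)
  h <- similarity_search(cdsR, cdsO)
  best <- do.call(rbind, lapply(split(h, h$query), function(x) x[1, ]))
  truth <- gm$truth$pairs
  expect_equal(best[truth$geneR, "subject"], truth$geneO,
               ignore_attr = TRUE)

  # random unrelated 300-bp sequences rarely share an 11-mer
  set.seed(7)
  n_hit <- sum(vapply(1:40, function(i) {
    a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    nrow(similarity_search(c(a = a), c(b = b))) > 0
  }, logical(1)))
  expect_lte(n_hit / 40, 0.05)
})

test_that("homeolog pairing uses reciprocal best hits with positional tie-break", {
  # constructed: query rank 6 with equal-score hits at ranks 5 and 40
  annot_r <- data.frame(id = sprintf("r%02d", 1:10), chromosome = "R1",
                        start = 1:10 * 1000L, end = 1:10 * 1000L + 500L,
                        strand = "+", stringsAsFactors = FALSE)
  annot_o <- data.frame(id = sprintf("o%02d", 1:40), chromosome = "O1",
                        start = 1:40 * 1000L, end = 1:40 * 1000L + 500L,
                        strand = "+", stringsAsFactors = FALSE)
  h_ro <- data.frame(query = "r06", subject = c("o05", "o40"),
                     score = c(100L, 100L), stringsAsFactors = FALSE)
  h_or <- data.frame(query = c("o05", "o40"), subject = "r06",
                     score = c(100L, 100L), stringsAsFactors = FALSE)
  pr <- pair_homeologs(h_ro, h_or, annot_r, annot_o)
  expect_equal(pr$geneO[pr$geneR == "r06"], "o05")  # closer rank wins

  expect_error(pair_homeologs(data.frame(query = "ghost", subject = "o05",
                                         score = 1L),
                              h_or, annot_r, annot_o), "unknown gene ids")

  # synthetic one-to-one annotation: every true pair recovered as primary,
  # and pairing is symmetric under swapping the R and O roles
  run <- run_homeolog_suite(8, omit_idx = integer(0), deleted_idx = integer(0))
  truth <- run$gm$truth$pairs
  expect_equal(nrow(run$pairs), nrow(truth))
  expect_true(all(run$pairs$method == "primary"))
  merged <- merge(run$pairs, truth, by = c("geneR", "geneO"))
  expect_equal(nrow(merged), nrow(truth))

  cdsO <- extract_cds(run$gm$genomeO, run$gm$annotO)
  cdsR <- extract_cds(run$gm$genomeR, run$gm$annotR)
  mirror <- pair_homeologs(similarity_search(cdsO, cdsR),
                           similarity_search(cdsR, cdsO),
                           run$gm$annotO, run$gm$annotR)
  expect_equal(mirror[order(mirror$geneR), c("geneR", "geneO")],
               stats::setNames(run$pairs[order(run$pairs$geneO),
                                         c("geneO", "geneR")],
                               c("geneR", "geneO")),
               ignore_attr = TRUE)
})

test_that("rescue recovers planted omissions and reports true deletions", {
  for (seed in 1:10) {
    run <- run_homeolog_suite(seed)
    truth <- run$gm$truth
    # all annotated pairs recovered
    merged <- merge(run$pairs, truth$pairs, by = c("geneR", "geneO"))
    expect_equal(nrow(merged), nrow(truth$pairs))
    # no gene in more than one pair across primary + rescue
    all_pairs <- rbind(run$pairs[, c("geneR", "geneO")],
                       run$rescue$pairs[, c("geneR", "geneO")])
    expect_false(anyDuplicated(all_pairs$geneR) > 0)
    expect_false(anyDuplicated(all_pairs$geneO) > 0)
    # omitted genes rescued; deleted-region genes genuinely missing
    expect_setequal(
      run$rescue$pairs$geneO[run$rescue$pairs$method == "rescue"],
      truth$rescuable)
    expect_setequal(run$rescue$missing$gene, truth$missing)
    # rescued models carry a valid ORF at >= 80% identity to the query
    if (nrow(run$rescue$new_models)) {
      cds_new <- extract_cds(run$gm$genomeR, run$rescue$new_models)
      expect_true(all(vapply(cds_new, validate_orf, logical(1))))
    }
  }
})

test_that("gene naming matches the systematic format and round-trips", {
  annot <- data.frame(
    id = c("g1", "g2", "g3"),
    chromosome = c("O1", "O1", "R7_O7"),
    start = c(100L, 5000L, 200L), end = c(1000L, 6000L, 900L),
    strand = "+", stringsAsFactors = FALSE)
  at <- data.frame(gene = "g1", at_id = "AT1G02140", method = "O",
                   stringsAsFactors = FALSE)
  nm <- name_genes(annot, at)
  expect_equal(unname(nm["g1"]), "Cbp.O1.g00001000.AT1G02140_O")
  expect_equal(unname(nm["g2"]), "Cbp.O1.g00002000.NA_B")
  expect_equal(parse_gene_name(nm["g3"])$chromosome, "R7_O7")

  parsed <- parse_gene_name(nm)
  expect_equal(parsed$number, c(1000L, 2000L, 1000L))
  expect_equal(parsed$at_id[1], "AT1G02140")
  expect_equal(parsed$method, c("O", "B", "B"))
  # numbers are multiples of 1000 and strictly increasing per chromosome
  expect_true(all(parsed$number %% 1000L == 0L))

  unsorted <- annot[c(2, 1, 3), ]
  expect_error(name_genes(unsorted), "sorted")
})
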