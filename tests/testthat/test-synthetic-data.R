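test_that("simulate_allotetraploid builds the tetraploid with exact truth", {
  # no exchange: pure O and R chromosome sets, no breakpoints
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 1)
  expect_setequal(names(sim$reference), c("O1", "O2", "R1", "R2"))
  expect_equal(nrow(sim$truth$he_breakpoints), 0L)

  # reciprocal HE: hybrid names, two mirrored breakpoints at the same position
  he <- simulate_allotetraploid(8, 100000, 0.01,
                                he_spec = list(chromosome = 7, fraction = 0.5),
                                seed = 2)
  expect_length(he$reference, 16L)
  expect_setequal(he$truth$he_breakpoints$chromosome, c("O7_R7", "R7_O7"))
  expect_equal(he$truth$he_breakpoints$position, rep(50000L, 2))
  seg <- he$truth$he_segments
  expect_equal(seg$source[seg$chromosome == "O7_R7"],
               rev(seg$source[seg$chromosome == "R7_O7"]))

  # every planted variant really differs between the subgenomes
  v <- sim$pair$variants
  expect_true(all(v$alleleO != v$alleleR))
  expect_equal(unname(substring(sim$pair$genomeO[v$chromosome[1]],
                                v$position[1], v$position[1])),
               v$alleleO[1])

  # variant count within 3 sigma of Binomial(L, rate) per genome
  big <- simulate_allotetraploid(1, 1000000, 0.01, seed = 3)
  n <- nrow(big$pair$variants)
  expect_lt(abs(n - 1e6 * 0.01), 3 * sqrt(1e6 * 0.01 * 0.99))

  # input validation
  expect_error(simulate_allotetraploid(1, 50000, 0.01), "degenerate")
  expect_error(simulate_allotetraploid(1, 100000, 0.3), "divergence")
  expect_error(simulate_allotetraploid(2, 100000, 0.01,
                                       he_spec = list(chromosome = 1,
                                                      fraction = 1.2)),
               "fraction")
})

test_that("seed determinism gives byte-identical outputs", {
  a <- simulate_allotetraploid(2, 100000, 0.01, seed = 42)
  b <- simulate_allotetraploid(2, 100000, 0.01, seed = 42)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
  write_genome_fasta(a$reference, fa)
  write_genome_fasta(b$reference, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  expect_identical(read_genome_fasta(fa), a$reference)
})

test_that("simulate_f2 respects crossover model and marker constraints", {
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 5)
  cp <- make_cross_parent(sim$reference, 30, seed = 6)

  # zero crossovers: per-chromosome genotype constant in every plant
  coh0 <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                      10, 0, 30, seed = 7)
  for (chrom in unique(coh0$markers$chromosome)) {
    g <- coh0$genotypes[coh0$markers$chromosome == chrom, , drop = FALSE]
    expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1L)))
  }

  # mean crossovers per chromosome per meiosis within 3 sigma of the rate
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     50, 1.5, 30, seed = 8)
  n_meioses <- 2 * 50 * length(sim$reference)
  expect_lt(abs(mean_crossovers(coh) - 1.5), 3 * sqrt(1.5 / n_meioses))

  # markers on different chromosomes segregate independently (n = 500)
  two <- list(O1 = cp$marker_positions$O1[1], R2 = cp$marker_positions$R2[1])
  cohI <- simulate_f2(sim$reference, cp$parent, two, 500, 1.5, 30, seed = 9)
  tab <- table(factor(cohI$genotypes[1, ], levels = 0:2),
               factor(cohI$genotypes[2, ], levels = 0:2))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)

  # unsorted or non-polymorphic marker positions rejected
  bad <- cp$marker_positions; bad$O1 <- rev(bad$O1)
  expect_error(simulate_f2(sim$reference, cp$parent, bad, 5, 1, 30), "sorted")
  expect_error(simulate_f2(sim$reference, sim$reference, cp$marker_positions,
                           5, 1, 30), "differ")
})

test_that("parental coverage tracks reflect subgenome of origin", {
  sim <- simulate_allotetraploid(2, 300000, 0.01,
                                 he_spec = list(chromosome = 1, fraction = 0.5),
                                 seed = 11)
  # zero cross-mapping: off-subgenome windows are exactly 0
  t0 <- simulate_parental_coverage(sim$reference, "O", 10000, 30, 0,
                                   segments = sim$truth$he_segments, seed = 12)
  expect_true(all(t0$values[["R2"]] == 0))
  expect_true(all(t0$values[["O2"]] >= 0))

  # mean on-subgenome depth within 3 sigma of Poisson expectation
  on <- t0$values[["O2"]]
  expect_lt(abs(mean(on) - 30), 3 * sqrt(30 / length(on)))

  # HE chromosome: maximal depth step sits at the truth breakpoint window
  tO <- simulate_parental_coverage(sim$reference, "O", 10000, 30, 0.02,
                                   segments = sim$truth$he_segments, seed = 13)
  hyb <- sim$truth$he_breakpoints$chromosome[1]
  v <- tO$values[[hyb]]
  step_win <- which.max(abs(diff(v)))
  truth_win <- sim$truth$he_breakpoints$position[1] %/% 10000
  expect_lte(abs(step_win - truth_win), 1L)

  expect_error(simulate_parental_coverage(sim$reference, "O", 400000, 30, 0.1,
                                          segments = sim$truth$he_segments),
               "window_size")
})

test_that("contig cutting conserves sequence and chimeras are recorded", {
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 21)
  ctg <- make_chimeric_contigs(sim$reference, 7, 0, truth = sim$truth, seed = 22)
  # conservation: contig segments tile each chromosome exactly
  expect_equal(sum(nchar(ctg$sequences)), sum(nchar(sim$reference)))
  for (chrom in names(sim$reference)) {
    seg <- ctg$contigs[ctg$contigs$chromosome == chrom, ]
    seg <- seg[order(seg$start), ]
    expect_equal(seg$start, c(1L, head(seg$end, -1) + 1L))
    expect_equal(max(seg$end), nchar(sim$reference[[chrom]]))
  }

  # chimeras: one junction each, joining an O piece to an R piece, and the
  # pieces match the source chromosomes at the recorded coordinates
  ch <- make_chimeric_contigs(sim$reference, 5, 5, truth = sim$truth, seed = 23)
  junc <- ch$truth$chimera_junctions
  expect_equal(nrow(junc), 5L)
  for (i in seq_len(nrow(junc))) {
    segs <- ch$contigs[ch$contigs$contig == junc$contig[i], ]
    expect_equal(nrow(segs), 2L)
    expect_setequal(substr(segs$chromosome, 1, 1), c("O", "R"))
    seq_c <- ch$sequences[[junc$contig[i]]]
    left <- substr(seq_c, 1, junc$position[i])
    expect_equal(left, substr(sim$reference[[segs$chromosome[1]]],
                              segs$start[1], segs$end[1]))
  }
  expect_error(make_chimeric_contigs(sim$reference, 0, 0), "n_contigs")
  expect_error(make_chimeric_contigs(sim$reference, 2, 100, truth = sim$truth),
               "eligible")
})

test_that("Hi-C pair simulator honours trans fraction and distance decay", {
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 31)
  cis_only <- simulate_hic_pairs(sim$reference, 5000, 1, 0, seed = 32)
  expect_true(all(cis_only$chrom1 == cis_only$chrom2))

  big <- simulate_allotetraploid(1, 300000, 0.01, seed = 33)
  pairs <- simulate_hic_pairs(big$reference, 100000, 1, 0, seed = 34)
  cm <- bin_contacts(pairs, 10000, nchar(big$reference))
  dec <- expected_decay(cm$cis[[1]])
  slope <- unname(coef(lm(log(dec[3:16]) ~ log(2:15)))[2])
  expect_lt(abs(slope - (-1)), 0.15)

  expect_error(simulate_hic_pairs(big$reference, 0, 1, 0), "n_pairs")
  expect_error(simulate_hic_pairs(big$reference, 10, -1, 0), "decay_exponent")
})
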