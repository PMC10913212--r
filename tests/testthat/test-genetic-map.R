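test_that("marker database keeps only homozygous-alternative SNPs", {
  recs <- data.frame(
    contig = "c1", position = c(10L, 20L, 30L, 40L, 50L),
    ref = c("A", "T", "C", "G", "A"), alt = c("G", "T", "C", "GA", "T"),
    gt = c("0/1", "1/1", "0/0", "1/1", "1/1"), dp = 30L,
    stringsAsFactors = FALSE)
  db <- suppressMessages(build_marker_db(recs))
  # het dropped, hom-ref dropped, indel dropped; T/T site and A/T site kept
  expect_equal(db$position, c(20L, 50L))
  expect_warning(build_marker_db(recs[0, ]), "empty")

  # synthetic F0: database positions equal the planted marker positions
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 41)
  cp <- make_cross_parent(sim$reference, 25, seed = 42)
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     10, 1, 30, seed = 43)
  db2 <- build_marker_db(f0_variant_records(coh))
  expect_equal(sort(db2$position[db2$contig == "O1"]),
               cp$marker_positions$O1)
})

test_that("marker states are called from genotype and depth evidence", {
  # per-plant VCF-style records
  db <- structure(data.frame(contig = "c1", position = c(5L, 9L),
                             ref = "A", alt = "T", stringsAsFactors = FALSE),
                  class = c("marker_db", "data.frame"))
  calls <- list(
    p1 = data.frame(contig = "c1", position = c(5L, 9L),
                    gt = c("0/1", "1/1"), dp = c(12L, 15L)),
    p2 = data.frame(contig = "c1", position = 5L, gt = "0/0", dp = 0L))
  depths <- matrix(c(10L, 0L), 2, 2, dimnames = list(c("c1:5", "c1:9"),
                                                     c("p1", "p2")))
  st <- call_marker_states(db, calls, depths = depths)
  expect_equal(st$states["c1:5", "p1"], 0L)   # het -> 0
  expect_equal(st$states["c1:9", "p1"], 1L)   # hom-alt -> 1
  expect_true(is.na(st$states["c1:5", "p2"])) # depth 0 -> missing
  expect_true(is.na(st$states["c1:9", "p2"])) # absent + depth 0 -> missing

  # full synthetic cohort at depth 30: states match planted genotypes >= 99%
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 44)
  cp <- make_cross_parent(sim$reference, 50, seed = 45)
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     50, 1.5, 30, seed = 46)
  db2 <- build_marker_db(f0_variant_records(coh))
  st2 <- call_marker_states(db2, coh)
  truth <- coh$genotypes[paste0(db2$source_chrom, ":", db2$source_pos), ] - 1L
  agree <- mean(st2$states == truth, na.rm = TRUE)
  expect_gte(agree, 0.99)
})

test_that("segregation filter applies the missingness and 1:2:1 rules", {
  expect_equal(round(segregation_chi2_threshold(0.05, 2), 2), 5.99)

  n <- 50
  mk_states <- function(n_m1, n_0, n_1, n_na = 0) {
    sample(c(rep(-1L, n_m1), rep(0L, n_0), rep(1L, n_1),
             rep(NA_integer_, n_na)))
  }
  set.seed(1)
  st <- rbind(
    balanced = mk_states(12, 26, 12),      # chi2 = 0.08 -> kept
    distorted = mk_states(50, 0, 0),       # chi2 = 150 -> removed
    gappy = mk_states(8, 12, 4, 26))       # 26/50 missing -> removed
  tab <- structure(list(states = st,
                        markers = data.frame(contig = "c1",
                                             position = 1:3 * 10L),
                        plants = paste0("p", 1:50)),
                   class = "marker_state_table")
  rownames(tab$states) <- c("c1:10", "c1:20", "c1:30")
  res <- filter_markers(tab)
  expect_equal(rownames(res$table$states), "c1:10")
  expect_setequal(res$log$reason, c("missingness", "segregation"))
  # frozen chi-square values from the 1:2:1 formula
  expect_equal(res$log$value[res$log$reason == "segregation"], 150)
  chi_balanced <- sum((c(12, 26, 12) - c(12.5, 25, 12.5))^2 / c(12.5, 25, 12.5))
  expect_equal(chi_balanced, 0.08)
  expect_lt(chi_balanced, segregation_chi2_threshold())

  # idempotence: filtering a filtered table removes nothing
  res2 <- filter_markers(res$table)
  expect_equal(nrow(res2$log), 0L)
  expect_identical(res2$table$states, res$table$states)
  # all removed -> error
  expect_error(filter_markers(structure(list(
    states = st[2:3, , drop = FALSE],
    markers = tab$markers[2:3, ], plants = tab$plants),
    class = "marker_state_table")), "all markers removed")
})

test_that("recombination events between markers are counted per chromosome copy", {
  s <- rep(0L, 50)
  expect_equal(count_interval_recombinations(s, s),
               list(events = 0L, informative = 50L, rate_per_100 = 0))
  # one plant flips -1 -> +1: two events (one per homologous chromosome)
  a <- rep(-1L, 50); b <- a; b[1] <- 1L
  r <- count_interval_recombinations(a, b)
  expect_equal(r$events, 2L)
  expect_equal(r$rate_per_100, 2)
  # missing plants drop out of the denominator
  b[2] <- NA
  expect_equal(count_interval_recombinations(a, b)$informative, 49L)
  expect_true(is.na(count_interval_recombinations(rep(NA_integer_, 3),
                                                  rep(0L, 3))$rate_per_100))

  # two unlinked markers: apparent rate far above what linkage allows (> 25)
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 51)
  cp <- make_cross_parent(sim$reference, 5, seed = 52)
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     50, 1.5, 30, seed = 53)
  m1 <- which(coh$markers$chromosome == "O1")[1]
  m2 <- which(coh$markers$chromosome == "R2")[1]
  rate <- count_interval_recombinations(coh$genotypes[m1, ] - 1L,
                                        coh$genotypes[m2, ] - 1L)$rate_per_100
  expect_gt(rate, 25)
})

test_that("misassembly detection flags only intervals with > 2 events", {
  # constructed: 2 events not flagged (strict rule), 3 events flagged
  a <- rep(c(-1L, 0L, 1L), c(12, 26, 12))
  b3 <- a; b3[1] <- 1L; b3[13] <- 1L      # 3 events vs a
  b2 <- b3; b2[13] <- 0L                  # 1 event vs b3
  tab <- structure(list(
    states = rbind(a, b3, b2),
    markers = data.frame(contig = "c1", position = c(10L, 20L, 30L)),
    plants = paste0("p", 1:50)), class = "marker_state_table")
  rownames(tab$states) <- c("c1:10", "c1:20", "c1:30")
  res <- detect_misassemblies(tab)
  expect_equal(nrow(res), 1L)   # only the 3-event interval; 1 and 2 events pass
  expect_equal(res$start, 10L)
  expect_equal(res$events, 3L)

  # clean synthetic contigs: no flags; planted chimeras: all recovered
  suite <- run_chimera_suite(101)
  expect_equal(suite$recall, 1)
  expect_equal(suite$false_positives, 0L)
})

test_that("contig coding applies the A/B/X interval rules inclusively", {
  st <- rbind(m1 = c(-1L, 1L, 0L, 1L, NA),
              m2 = c(-0.6, 1L, 0L, 0L, NA),
              m3 = c(-1L, 1L, 0L, NA, NA))
  st <- matrix(as.numeric(st), 3, 5, dimnames = list(c("c1:1", "c1:2", "c1:3"),
                                                     paste0("p", 1:5)))
  tab <- structure(list(states = st,
                        markers = data.frame(contig = "c1", position = 1:3),
                        plants = paste0("p", 1:5)),
                   class = "marker_state_table")
  cc <- code_contigs(tab)
  # means: -0.8667->A? no: mean(-1,-0.6,-1) = -0.8667 -> A (within [-1,-0.8])
  expect_equal(unname(cc$codes["c1", ]), c("A", "B", "X", NA, NA))

  # boundary values: interval ends included, intermediate undefined
  one <- function(mean_states) {
    m <- matrix(mean_states, 1, length(mean_states),
                dimnames = list("cX:1", paste0("p", seq_along(mean_states))))
    t2 <- structure(list(states = m,
                         markers = data.frame(contig = "cX", position = 1L),
                         plants = colnames(m)),
                    class = "marker_state_table")
    unname(code_contigs(t2)$codes[1, ])
  }
  expect_equal(one(c(-0.8, 0.8, 0.2, -0.2, 0.5, -0.5, 0.79)),
               c("A", "B", "X", "X", NA, NA, NA))
})

test_that("linkage grouping separates chromosomes and orders contigs", {
  # single contig -> one group of one
  g1 <- matrix(c(0, 1, -1, 0), 1, 4, dimnames = list("only", paste0("p", 1:4)))
  lg1 <- group_and_order(g1)
  expect_length(lg1$groups, 1L)

  # constructed pair: rf ~ 0.02 -> same group, rf ~ 0.5 -> different groups
  set.seed(60)
  base <- sample(c(-1L, 0L, 1L), 200, replace = TRUE, prob = c(.25, .5, .25))
  near <- base; flip <- sample(200, 4); near[flip] <- base[flip] - 1L
  far <- sample(c(-1L, 0L, 1L), 200, replace = TRUE, prob = c(.25, .5, .25))
  m <- rbind(a = base, b = near, c = far)
  lg2 <- group_and_order(m)
  expect_equal(unname(lg2$membership["a"]), unname(lg2$membership["b"]))
  expect_false(lg2$membership["a"] == lg2$membership["c"])

  # rf estimator converges at n = 500: tightly linked loci -> near 0,
  # unlinked loci -> 0.5 (within +-0.05)
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 61)
  cp <- make_cross_parent(sim$reference, 50, seed = 62)
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     500, 1.5, 30, seed = 63)
  g <- coh$genotypes - 1L
  o1 <- which(coh$markers$chromosome == "O1")
  r2 <- which(coh$markers$chromosome == "R2")
  rfm <- rf_matrix(g[c(o1[1:2], r2[1]), ])
  expect_lt(rfm$rf[1, 2], 0.05 +
              1.5 * diff(coh$markers$position[o1[1:2]]) / 1e5)
  expect_lt(abs(rfm$rf[1, 3] - 0.5), 0.05)

  # contig with zero informative plants -> flagged singleton
  m2 <- rbind(a = base, z = rep(NA_integer_, 200))
  lg3 <- group_and_order(m2)
  expect_equal(lg3$flagged_singletons, "z")
  expect_length(lg3$groups, 2L)

  # oracle: membership equals connected components (independent BFS) of the
  # strict-linkage graph when groups are well separated
  suite <- run_map_pipeline(71, n_anc = 2)
  lg <- suite$groups
  rf <- lg$rf
  adj <- !is.na(rf) & rf < 0.1
  diag(adj) <- FALSE
  comp <- rep(0L, nrow(adj)); cid <- 0L
  for (v in seq_len(nrow(adj))) {
    if (comp[v] > 0L) next
    cid <- cid + 1L; queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0L) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & comp == 0L))
    }
  }
  bfs_groups <- split(rownames(rf), comp)
  # end-joining can only merge strict-linkage components, never split them
  for (members in bfs_groups) {
    expect_length(unique(lg$membership[members]), 1L)
  }

  # full pipeline on a 4-chromosome system: pure groups, consistent order
  expect_true(groups_are_pure(lg))
  expect_length(lg$groups, 4L)
  rhos <- vapply(lg$groups, group_order_rho, numeric(1))
  expect_gte(median(rhos), 0.95)
  expect_true(all(rhos >= 0.8))
})

test_that("recombination counts per linkage group follow the crossover model", {
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = 81)
  cp <- make_cross_parent(sim$reference, 40, seed = 82)

  # zero crossover rate: all per-chromosome totals zero
  coh0 <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                      20, 0, 30, seed = 83)
  db <- build_marker_db(f0_variant_records(coh0))
  st <- call_marker_states(db, coh0)
  rows <- split(rownames(st$states), st$markers$contig)
  rep0 <- recombinations_per_chromosome(st, rows)
  expect_true(all(rep0$per_plant == 0))

  # rate 1.5: mean events per plant per chromosome within 3 sigma of 2 * 1.5
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     50, 1.5, 30, seed = 84)
  st2 <- call_marker_states(build_marker_db(f0_variant_records(coh)), coh)
  rows2 <- split(rownames(st2$states), st2$markers$contig)
  rep2 <- recombinations_per_chromosome(st2, rows2)
  grand_mean <- mean(rep2$per_plant)
  n_cells <- length(rep2$per_plant)
  expect_lt(abs(grand_mean - 3), 3 * sqrt(3 / n_cells) + 0.15)

  # a chromosome with suppressed recombination has the lowest mean
  pos <- cp$marker_positions
  cohA <- simulate_f2(sim$reference["O1"], cp$parent["O1"], pos["O1"],
                      50, 0.1, 30, seed = 85)
  cohB <- simulate_f2(sim$reference["R1"], cp$parent["R1"], pos["R1"],
                      50, 1.5, 30, seed = 86)
  stA <- call_marker_states(build_marker_db(f0_variant_records(cohA)), cohA)
  stB <- call_marker_states(build_marker_db(f0_variant_records(cohB)), cohB)
  comb <- structure(list(states = rbind(stA$states, stB$states),
                         markers = rbind(stA$markers, stB$markers),
                         plants = stA$plants),
                    class = "marker_state_table")
  rep3 <- recombinations_per_chromosome(
    comb, split(rownames(comb$states), comb$markers$contig))
  means <- rep3$summary$mean_events
  names(means) <- rep3$summary$group
  expect_equal(names(which.min(means)), "O1")

  # unordered / unknown rows rejected
  expect_error(recombinations_per_chromosome(st, list(g = "nonexistent")),
               "missing from table")
})
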