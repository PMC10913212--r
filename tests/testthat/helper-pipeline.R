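# Shared pipeline runners used across test files. All randomness is seeded.

# Full map pipeline at the study scale: 16-chromosome tetraploid (8 per
# subgenome, 300 kb), ~50 markers and ~10 contigs per chromosome, 50 plants,
# Poisson(1.5) crossovers, depth 30.
run_map_pipeline <- function(seed, n_anc = 8, chrom_length = 300000,
                             markers_per_chrom = 50, contigs_per_chrom = 10,
                             n_plants = 50, crossover_rate = 1.5,
                             depth_mean = 30, he = TRUE) {
  sim <- simulate_allotetraploid(
    n_anc, chrom_length, 0.01,
    he_spec = if (he) list(chromosome = min(7, n_anc), fraction = 0.5),
    seed = seed)
  cp <- make_cross_parent(sim$reference, markers_per_chrom, seed = seed + 1000)
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     n_plants, crossover_rate, depth_mean, seed = seed + 2000)
  ctg <- make_chimeric_contigs(sim$reference, contigs_per_chrom, 0,
                               truth = sim$truth, seed = seed + 3000)
  db <- build_marker_db(f0_variant_records(coh, ctg$contigs))
  st <- call_marker_states(db, coh)
  flt <- suppressMessages(filter_markers(st))
  codes <- code_contigs(flt$table)
  lg <- group_and_order(codes, states = flt$table)
  list(sim = sim, cohort = coh, contigs = ctg, states = st,
       filtered = flt$table, codes = codes, groups = lg)
}

# Chimera/misassembly suite at physically scaled desk conditions: 2 ancestral
# chromosomes x 100 kb, 200 markers/chromosome (~500 bp spacing), 5 contigs
# per chromosome, 5 planted chimeras, crossover rate 0.05, depth 30, n = 50.
# Detection runs on the missingness-filtered table (the event-count statistic
# is invariant to segregation distortion; see the methods vignette).
run_chimera_suite <- function(seed) {
  sim <- simulate_allotetraploid(2, 100000, 0.01, seed = seed)
  cp <- make_cross_parent(sim$reference, 200, seed = seed + 1000)
  coh <- simulate_f2(sim$reference, cp$parent, cp$marker_positions,
                     50, 0.05, 30, seed = seed + 2000)
  ctg <- make_chimeric_contigs(sim$reference, 5, 5, truth = sim$truth,
                               seed = seed + 3000)
  db <- build_marker_db(f0_variant_records(coh, ctg$contigs))
  st <- call_marker_states(db, coh)
  flt <- suppressMessages(filter_markers(st, chi2_threshold = Inf))
  mis <- suppressMessages(detect_misassemblies(flt$table))
  junc <- ctg$truth$chimera_junctions
  hit <- vapply(seq_len(nrow(junc)), function(i) {
    any(mis$contig == junc$contig[i] &
          mis$start <= junc$position[i] & mis$end >= junc$position[i])
  }, logical(1))
  list(recall = mean(hit), false_positives = sum(!(mis$contig %in% junc$contig)),
       flagged = mis, junctions = junc)
}

# Chromosome of origin encoded in synthetic contig names.
contig_chromosome <- function(contig) sub("^ctg_(.*)_[0-9]+$", "\\1", contig)

# Membership purity: every linkage group contains contigs of one chromosome.
groups_are_pure <- function(lg) {
  src <- contig_chromosome(names(lg$membership))
  all(vapply(split(src, lg$membership),
             function(x) length(unique(x)) == 1L, logical(1)))
}

# |Spearman rho| between recovered within-group order and true contig order.
group_order_rho <- function(members) {
  ord <- as.integer(sub("^ctg_.*_([0-9]+)$", "\\1", members))
  if (length(ord) < 3L) return(1)
  abs(stats::cor(seq_along(ord), ord, method = "spearman"))
}

# HE-chromosome coverage + call for one seed (depth 30, 10-kb windows).
run_he_call <- function(seed, cross_mapping_rate = 0.05) {
  sim <- simulate_allotetraploid(2, 300000, 0.01,
                                 he_spec = list(chromosome = 1, fraction = 0.5),
                                 seed = seed)
  tO <- simulate_parental_coverage(sim$reference, "O", 10000, 30,
                                   cross_mapping_rate,
                                   segments = sim$truth$he_segments,
                                   seed = seed + 100)
  tR <- simulate_parental_coverage(sim$reference, "R", 10000, 30,
                                   cross_mapping_rate,
                                   segments = sim$truth$he_segments,
                                   seed = seed + 200)
  bp <- sim$truth$he_breakpoints
  calls <- lapply(bp$chromosome, function(ch)
    call_subgenome(coverage_profile(tO, tR, ch)))
  list(truth = bp, calls = calls, sim = sim, track_o = tO, track_r = tR)
}

# Homeolog pairing + rescue end-to-end for one seed.
run_homeolog_suite <- function(seed, n_genes = 20, omit_idx = c(4, 11),
                               deleted_idx = 17) {
  gm <- simulate_gene_models(100000, n_genes, 900, 0.01,
                             omit_idx = omit_idx, deleted_idx = deleted_idx,
                             seed = seed)
  cdsO <- extract_cds(gm$genomeO, gm$annotO)
  cdsR <- extract_cds(gm$genomeR, gm$annotR)
  pairs <- pair_homeologs(similarity_search(cdsR, cdsO),
                          similarity_search(cdsO, cdsR),
                          gm$annotR, gm$annotO)
  rescue <- rescue_missing(pairs, gm$annotR, gm$annotO,
                           gm$genomeR, gm$genomeO)
  list(gm = gm, pairs = pairs, rescue = rescue)
}

# Hi-C junction verdicts on the true and translocation-modified reference.
run_hic_control <- function(seed, n_pairs = 100000) {
  sim <- simulate_allotetraploid(2, 300000, 0.01,
                                 he_spec = list(chromosome = 1, fraction = 0.5),
                                 seed = seed)
  bp <- sim$truth$he_breakpoints
  pairs <- simulate_hic_pairs(sim$reference, n_pairs, 1, 0.05, seed = seed + 10)
  lens <- nchar(sim$reference)
  cm_true <- bin_contacts(pairs, 10000, lens)
  lifted <- liftover_translocation(pairs, bp$chromosome[1], bp$chromosome[2],
                                   bp$position[1], bp$position[2])
  cm_mod <- bin_contacts(lifted, 10000, lens)
  verdict <- function(cm, i)
    junction_score(cm$cis[[bp$chromosome[i]]], bp$position[i],
                   flank = 50000, bin_size = 10000)$verdict
  list(true = vapply(seq_len(nrow(bp)), function(i) verdict(cm_true, i),
                     character(1)),
       modified = vapply(seq_len(nrow(bp)), function(i) verdict(cm_mod, i),
                         character(1)))
}
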