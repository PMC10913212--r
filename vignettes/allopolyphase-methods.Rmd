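---
title: "Methods and design of allopolyphase"
author: "allopolyphase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of allopolyphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`allopolyphase` packages the computational core of a subgenome-resolved
allotetraploid genome project: genetic-map-based misassembly detection,
coverage-based subgenome assignment with homeologous-exchange (HE)
breakpoint detection, homeolog pairing and systematic naming,
pseudoalignment construction, Patterson's D / f4-ratio statistics, and
Hi-C junction validation. This vignette explains the models behind each
stage, the tunable parameters and their defaults, the numerical decisions
taken where the design was genuinely open, and what the synthetic-data
tests do and do not demonstrate about real data.

## The synthetic allotetraploid

All testing rests on a miniature allotetraploid with complete ground
truth. A random ancestor is simulated; the O subgenome equals the
ancestor and the R subgenome carries substitutions at a fixed per-bp rate
(default 1%, of the order of two plant species that diverged about one
million years ago). Divergence is substitution-only, so homeologous
coordinates are identical between subgenomes and every downstream truth
comparison is exact. One chromosome pair can undergo a reciprocal HE,
producing hybrid chromosomes named like `O7_R7` / `R7_O7` whose source
subgenome switches at the breakpoint; an optional `deleted_region`
replaces an O-subgenome interval with non-homologous random sequence,
modelling a lineage-specific deletion while keeping coordinates aligned.

The F2 generator gives every plant two independent gametes per
chromosome, each a mosaic of the two parental haplotypes with a
Poisson-distributed crossover count (no interference — the detection
rules used downstream do not depend on it) and uniform crossover
positions. Sequencing is emulated by Poisson depth and binomial allele
sampling, so genotype calls carry realistic low-coverage errors (a
heterozygote with few reads can collapse to a homozygote call).

Default scales are chosen so a full run takes seconds: 16 chromosomes of
300 kb for map construction, 100-kb chromosomes for the misassembly
suite, 50 plants throughout. Two desk-scale compressions matter when
interpreting results. First, with 1.5 crossovers per 300-kb chromosome
the per-bp crossover density is roughly sixty times that of a real
~17-Mb chromosome, so genetic distances per kb are hugely inflated.
Second, sequence-level effects of real data — repeats, pericentromeres,
mapping artefacts, sequencing error models — are not modelled at all, so
passing tests demonstrate the correctness of the algorithms under their
stated models, not robustness to those artefacts.

Coordinates are 1-based and closed everywhere inside the package, the
natural convention for R string handling; emitted VCF-like records are
1-based and bedGraph window starts 0-based, as those formats require.

## Genetic map: states, filters, misassembly rule

Marker states follow the standard F2 coding: −1 homozygous reference, 0
heterozygous, 1 homozygous for the second parent's allele, missing when
depth is below `min_depth` (default 2). Markers missing in more than
half the plants are removed, then markers whose (n₋₁, n₀, n₁) counts
violate the Mendelian 1:2:1 expectation by Pearson's criterion,
χ² > 5.99 — the 5% critical value at 2 degrees of freedom, exposed as
`segregation_chi2_threshold()`.

Recombination events between two markers are counted as Σ|g₁ − g₂| over
plants informative for both, i.e. one event per homologous chromosome,
and rates are reported per 100 chromosomes (denominator 2n). Under this
statistic two unlinked markers show an expected 37.5 events per 100
chromosomes — far above anything physical linkage produces — which is
exactly the misassembly signature: more than two events between
*adjacent* markers flags the interval as a chimeric join
(`detect_misassemblies`, strict `> 2`).

One pipeline-order subtlety is documented here deliberately. At desk
scale a low-recombination chromosome segregates almost as a single
locus, so when its 50-plant genotype draw happens to be distorted the
1:2:1 filter removes *all* of its markers at once. The event-count
statistic itself is invariant to segregation distortion, so the
misassembly test suite applies only the missingness filter before
detection, while map construction keeps the full filter chain. With real
marker densities (sub-kb spacing against multi-Mb chromosomes) the
distinction is immaterial.

## Linkage grouping

The recombination fraction between two loci is estimated by de-biasing
the event fraction: with est = events/(2n), E[est] = r − r²/2 under true
recombination fraction r (the genotype difference saturates at 0.375 for
unlinked loci), so `rf = 1 − sqrt(1 − 2·est)`, which converges to r —
in particular to 0.5 for unlinked pairs. Between *contigs*, rf is taken
as the minimum de-biased estimate over all marker pairs (the
closest-marker rf, i.e. the inter-contig gap), computed at the
marker-state level: contig consensus codes (A/B/X) lose every plant with
a crossover inside the contig, and at n = 50 that loss is fatal for
grouping accuracy.

Grouping is two-staged. Stage one forms single-linkage components over
edges with rf < 0.1: the exact lower tail of the unlinked estimate below
0.1 is < 10⁻⁹ per pair (computed by convolving the per-plant |Δg|
distribution with cell probabilities 0.375/0.5/0.125), so with ~12,000
unlinked contig pairs in the default 16-chromosome simulation the
expected number of contaminated components is ≈ 0. Stage two orders each
component along the minimum-spanning-tree diameter path and then
iteratively joins components — closest first — when the minimum rf
between their *terminal* contigs is below `rf_link_threshold`
(default 0.2; exact unlinked tail ≈ 3·10⁻⁶ per pair). Restricting joins
to ordered ends reflects map linearity: true fragments of one chromosome
join end-to-end, while a spurious low rf to an interior contig of
another group cannot cause a merge. Within-group order is finally
refined by a deterministic local search (adjacent swaps and single
relocations minimising the summed rf between consecutive contigs); ties
and orientation are resolved lexicographically, so results are
reproducible to the byte.

The residual stochasticity of group recovery is a property of the data,
not the algorithm: when the segregation filter removes a spatially
correlated block of markers, the resulting marker desert can span an rf
of 0.25–0.35 at desk scale, and no statistic at n = 50 can confidently
distinguish that from unlinked (the exact tails overlap). Such runs
split one chromosome into two groups. Conversely, about once in
thousands of chromosome pairs a meiotic sampling fluke produces an
unlinked rf below threshold. Both behaviours are visible in the test
suite's multi-seed statistics and mirror the original mapping
experience, where the external grouping tool also had to be re-run with
adjusted cut-offs to reach the chromosome number.

## Subgenome assignment

Windowed parental depth is contrasted as log₂((dO + pc)/(dR + pc)) with
pseudocount 1. `call_subgenome` applies recursive binary segmentation:
each candidate split minimises within-segment squared error and is
accepted while both sides span at least `min_segment_windows` (5) and
their means differ by at least `min_abs_log_ratio` (1.0, i.e. a 2-fold
coverage bias — chosen so the default simulated contrast, on-target
depth 30 versus 5% cross-mapping, is decisive by a wide margin). The
mean-difference acceptance rule doubles as the stopping criterion, which
keeps the segmentation free of a separate penalty parameter. Segments
are labelled by mean sign, same-label neighbours merged, and a
chromosome is `hybrid` exactly when both sources remain; windows with
|log-ratio| below the threshold count against the call's confidence.
Breakpoints are reported at window boundaries, so their resolution is
one window (10 kb by default).

Read-assignment validation mimics the mapping-rate argument for
subgenome separability without a read mapper: reads sampled from one
parental genome are assigned to the combined-reference chromosome
sharing the most *diagnostic* 31-mers (k-mers unique to one chromosome;
ties unassigned). At 1% divergence and 150-bp reads the expected correct
fraction is the probability of carrying at least one diagnostic SNP,
1 − 0.99¹⁵⁰ ≈ 0.78, with essentially no wrong assignments — the
simulation reproduces this closely, and at 5% divergence with 300-bp
reads assignment is essentially perfect.

## Homeolog pairing, rescue and naming

CDS-vs-CDS similarity uses exact 11-mer seeds and ungapped extension
(match +1, mismatch −1), scoring each query/subject diagonal by its
maximum-scoring segment; at the 1% divergence of surviving homeolog
pairs the true diagonal dominates every alternative, and two random
300-bp sequences share an 11-mer in well under 5% of trials. Reciprocal
best hits are paired first; equal-score alternatives are resolved by
ordinal position along the chromosome (minimum rank difference — rank
rather than coordinate distance, because coordinates of the two
subgenomes need not be commensurate in real data); remaining
one-directional best hits are accepted up to a rank distance of 10.
Unpaired genes trigger an interval-constrained rescue: the region of the
other subgenome between the partners of the gene's nearest paired
neighbours is scanned (both strands) with the gene's CDS, and a hit with
identity ≥ 0.8 covering at least half the query becomes a new gene model
and rescue pair, provided its projected region carries a valid ORF and
overlaps no existing gene. The identity and coverage cut-offs are
declared defaults: at 1% divergence true partners score ≈ 0.99 identity,
so 0.8 separates them from background by an order of magnitude. Genes in
a deleted region have no homologous sequence to find and are reported as
genuinely missing — the correct biological answer, not a failure.

Names follow `Cbp.<chromosome>.g%08d.<At ortholog>_<letter>` with gene
numbers spaced by 1000 along each chromosome to leave room for later
insertions; the letter records the origin of the *A. thaliana*
correspondence (O = orthogroup, B = best similarity hit; B is also used
when no correspondence exists, with `NA` in the ortholog slot).
`parse_gene_name` inverts the format exactly.

## Pseudoalignments and Patterson's D

The site list is the union of biallelic SNPs over samples (indels
excluded; conflicting alternative alleles kept and logged). Sample
sequences substitute each listed site by the rules: depth < 4 → `N`,
homozygous alternative → alternative base, heterozygote → two-base IUPAC
code, no call at adequate depth → reference. All rows have the region's
length, so the alignment is positionally homologous by construction.

`patterson_d` works on derived-allele frequencies with the outgroup
defining the ancestral allele (sites where the outgroup is polymorphic,
more than two alleles segregate, or any population is entirely `N` are
skipped). Heterozygous IUPAC bases contribute allele frequency 0.5 —
dropping them would discard most sites of a selfing tetraploid's
heterozygous accessions. The Z score uses a delete-one block jackknife
over blocks of 1000 consecutive used sites (sites, not bp, so block
count is independent of site density); the f4-ratio splits P3 into two
halves and replaces P2 by the second half in the denominator, the
standard subset construction. The quartet simulator is coalescent-free:
it plants ABBA/BABA/BBAA/singleton site patterns directly, with
introgression converting P3-derived sites into shared-derived ones, so
the estimator's sign, calibration (D ≈ planted excess), and null
behaviour (|Z| < 3) are tested without tree simulation machinery.

## Hi-C junction validation

Pairs are binned symmetrically (each cis pair increments (i,j) and
(j,i), so matrix totals are twice the pair count). The distance-decay
expectation is the mean count per off-diagonal distance of the same
matrix; a junction's score is observed over expected contacts among bin
pairs spanning it within a flank. Verdicts use declared thresholds: gap
below 0.2, supported at or above 0.5. These were fixed from the decay
model — for an absent junction the observed cross-block count is near
zero while the expectation is large, and for a real one the ratio
concentrates near 1, so any thresholds well inside (0, 1) separate them;
the simulated-translocation control in the test suite verifies perfect
separation at 10⁵ pairs over 20 seeds. The cis pair simulator draws
separations with the locus-pair density ∝ (L − s)·s^(−α) (the (L − s)
factor is the number of position pairs at separation s), which makes the
per-bin-pair decay follow s^(−α) exactly; binned against a reference
carrying an artificial reciprocal translocation, the same pairs produce
the characteristic empty anti-diagonal block. Re-mapping of reads onto
the modified reference is represented by exact coordinate liftover,
which is faithful here because simulated pairs are exact coordinates.

## Problem sizes

The test suite and acceptance script run entirely on simulated data at
the following scales, chosen so the full suite completes in a few
minutes on one CPU: map construction on 16 × 300-kb chromosomes
(~800 markers, 160 contigs, 50 plants); the misassembly suite on
2 × 2 × 100-kb chromosomes with 200 markers per chromosome and 5 planted
chimeras over 20 seeds; HE-breakpoint recovery over 20 seeds at depth
30; homeolog recovery on 20-gene chromosomes over 10 seeds; D-statistic
checks at 50,000 sites (planted introgression) and 40 × 5,000 sites
(null); Hi-C controls at 50,000–100,000 pairs over 20 seeds.

## Known limitations

* Substitution-only divergence keeps subgenome coordinates equal; real
  subgenomes differ by indels and rearrangements, which the truth
  bookkeeping does not cover (the deleted-region analog is the one
  exception).
* The misassembly rule's false-positive behaviour depends on the ratio
  of crossover density to marker spacing; the desk-scale defaults
  emulate the favourable regime of dense real marker sets, and the
  grouping stage inherits genuine ambiguity wherever the segregation
  filter creates marker deserts.
* The k-mer read-assignment validator and the CDS similarity scorer are
  exact-match methods: adequate at simulated divergences, not
  replacements for a read mapper or aligner on real, repeat-rich data.
* Hi-C matrices are unnormalised (no ICE/KR); junction scoring relies on
  the raw decay, which is appropriate for the simulated pairs and for
  the qualitative gap/support decision it implements.
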