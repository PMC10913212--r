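#' Simulate quartet site patterns with optional introgression
#'
#' A coalescent-free site-pattern generator for exercising the ABBA-BABA
#' machinery. Each polymorphic site receives a derived-allele pattern over
#' (P1, P2, P3); incomplete lineage sorting contributes ABBA and BABA
#' patterns in equal proportion `p_ils / 2` each, `p_bbaa` sites carry the
#' concordant BBAA pattern, and the remainder are singletons. Introgression
#' from P3 into P2 then converts each site at which P3 (and not P2) carries
#' the derived allele into a shared-derived site with probability
#' `introgression` - the directional excess of ABBA that Patterson's D
#' detects. The outgroup is always ancestral.
#'
#' @param n_sites Number of polymorphic sites.
#' @param introgression Probability in [0, 1) that a P3-derived site is
#'   transferred into P2.
#' @param p_ils Total ILS (ABBA + BABA) fraction.
#' @param p_bbaa Concordant-pattern fraction.
#' @param seed Integer RNG seed.
#' @param as_sequences If TRUE, return one haploid sequence per population
#'   (derived = `"T"`, ancestral = `"A"`) plus a `groups` list suitable for
#'   [patterson_d()]; otherwise a derived-allele frequency data frame with
#'   columns `p1`, `p2`, `p3`, `p3a`, `p3b`.
#' @return See `as_sequences`.
#' @export
simulate_quartet_sites <- function(n_sites, introgression = 0,
                                   p_ils = 0.2, p_bbaa = 0.2,
                                   seed = 1L, as_sequences = FALSE) {
  stopifnot(n_sites > 0, introgression >= 0, introgression < 1,
            p_ils + p_bbaa < 1)
  with_seed_or_not(seed, {
    p_single <- (1 - p_ils - p_bbaa) / 3
    pat <- sample(c("ABBA", "BABA", "BBAA", "s1", "s2", "s3"), n_sites,
                  replace = TRUE,
                  prob = c(p_ils / 2, p_ils / 2, p_bbaa,
                           p_single, p_single, p_single))
    d1 <- as.numeric(pat %in% c("BABA", "BBAA", "s1"))
    d2 <- as.numeric(pat %in% c("ABBA", "BBAA", "s2"))
    d3 <- as.numeric(pat %in% c("ABBA", "BABA", "s3"))
    if (introgression > 0) {
      flow <- d3 == 1 & d2 == 0 & runif(n_sites) < introgression
      d2[flow] <- 1
    }
    if (!as_sequences) {
      return(data.frame(p1 = d1, p2 = d2, p3 = d3, p3a = d3, p3b = d3))
    }
    base <- function(d) paste(ifelse(d == 1, "T", "A"), collapse = "")
    seqs <- c(P1_s = base(d1), P2_s = base(d2),
              P3_s1 = base(d3), P3_s2 = base(d3),
              OUT_s = base(rep(0, n_sites)))
    list(sequences = seqs,
         groups = list(P1 = "P1_s", P2 = "P2_s",
                       P3 = c("P3_s1", "P3_s2"), O = "OUT_s"))
  })
}
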