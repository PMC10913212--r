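#' Pairwise recombination-fraction estimates between coded contigs
#'
#' Contig codes are mapped to genotypes (A = -1, X = 0, B = 1) and for every
#' pair the event fraction `est = sum(|g_i - g_j|) / (2 * informative)` is
#' computed over pairwise-complete plants. Because an F2 genotype difference
#' saturates (for true recombination fraction r, E\[est\] = r - r^2/2, i.e.
#' 0.375 for unlinked loci), the estimate is de-biased by inverting that
#' relation: `rf = 1 - sqrt(1 - 2 * est)` (clipped to [0, 1]), which
#' converges to r - in particular to 0.5 for unlinked pairs.
#'
#' @param codes A `contig_code_table`, or a numeric genotype matrix
#'   (rows = contigs, values in \{-1, 0, 1, NA\}).
#' @return List with `rf` (symmetric matrix of de-biased estimates),
#'   `informative` (pairwise plant counts).
#' @export
rf_matrix <- function(codes) {
  g <- codes_to_genotypes(codes)
  n <- nrow(g)
  rf <- matrix(NA_real_, n, n, dimnames = list(rownames(g), rownames(g)))
  inf <- matrix(0L, n, n, dimnames = dimnames(rf))
  for (i in seq_len(n)) {
    rf[i, i] <- 0
    inf[i, i] <- sum(!is.na(g[i, ]))
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      m <- sum(ok)
      inf[i, j] <- inf[j, i] <- m
      if (m > 0L) {
        est <- sum(abs(g[i, ok] - g[j, ok])) / (2 * m)
        r <- 1 - sqrt(max(0, 1 - 2 * min(est, 0.5)))
        rf[i, j] <- rf[j, i] <- r
      }
    }
  }
  list(rf = rf, informative = inf)
}

codes_to_genotypes <- function(codes) {
  if (inherits(codes, "contig_code_table")) {
    map <- c(A = -1, X = 0, B = 1)
    g <- matrix(unname(map[codes$codes]), nrow(codes$codes),
                ncol(codes$codes), dimnames = dimnames(codes$codes))
    g
  } else {
    as.matrix(codes)
  }
}

#' Between-contig recombination fractions from marker states
#'
#' Estimates the recombination fraction between two contigs as the minimum
#' de-biased estimate over all pairs of their markers - effectively the rf
#' of the mutually closest markers, i.e. the inter-contig gap. Unlike the
#' contig-code estimate, this keeps every plant whose markers were called
#' (plants recombinant *within* a contig are not lost), so the estimates
#' are sharp enough for reliable linkage grouping at F2 sample sizes.
#'
#' @param table A `marker_state_table` whose markers carry the contig ids
#'   to be grouped.
#' @return List with `rf` (symmetric matrix over contigs) and `informative`
#'   (informative plant count of the minimising marker pair).
#' @export
contig_rf_matrix <- function(table) {
  st <- table$states
  mk <- table$markers
  contigs <- sort(unique(mk$contig))
  rows_of <- lapply(contigs, function(ctg) {
    rows <- which(mk$contig == ctg)
    rows[order(mk$position[rows])]
  })
  names(rows_of) <- contigs
  n <- length(contigs)

  # pairwise marker-level event and informative counts via indicator algebra
  Am <- (!is.na(st) & st == -1L) + 0
  A0 <- (!is.na(st) & st == 0L) + 0
  Ap <- (!is.na(st) & st == 1L) + 0
  events <- Am %*% t(A0) + A0 %*% t(Am) + A0 %*% t(Ap) + Ap %*% t(A0) +
    2 * (Am %*% t(Ap) + Ap %*% t(Am))
  informative <- (Am + A0 + Ap) %*% t(Am + A0 + Ap)
  est <- events / (2 * pmax(informative, 1L))
  est[informative == 0L] <- NA_real_
  mrf <- 1 - sqrt(pmax(1 - 2 * pmin(est, 0.5), 0))

  rf <- matrix(NA_real_, n, n, dimnames = list(contigs, contigs))
  inf <- matrix(0L, n, n, dimnames = dimnames(rf))
  for (i in seq_len(n)) {
    rf[i, i] <- 0
    inf[i, i] <- sum(!is.na(st[rows_of[[i]][1L], ]))
    for (j in seq_len(i - 1L)) {
      block <- mrf[rows_of[[i]], rows_of[[j]], drop = FALSE]
      if (all(is.na(block))) next
      best <- which(block == min(block, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      rf[i, j] <- rf[j, i] <- block[best[1L], best[2L]]
      inf[i, j] <- inf[j, i] <-
        informative[rows_of[[i]][best[1L]], rows_of[[j]][best[2L]]]
    }
  }
  list(rf = rf, informative = inf)
}

# Order a set of contigs along the diameter path of the MST of their rf
# graph; ties and orientation broken lexicographically.
order_along_mst <- function(members, rf) {
  if (length(members) <= 2L) return(sort(members))
  w <- rf[members, members]
  w[is.na(w)] <- 1
  gg <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(gg, weights = igraph::E(gg)$weight)
  d <- igraph::distances(mst, weights = igraph::E(mst)$weight)
  far <- which(d == max(d), arr.ind = TRUE)
  ends <- t(apply(far, 1L, function(ij)
    sort(c(rownames(d)[ij[1]], rownames(d)[ij[2]]))))
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
  origin <- ends[1, 1]
  ord <- members[order(d[origin, members], members)]
  refine_order(ord, rf)
}

# Deterministic local search: adjacent swaps and single relocations that
# reduce the summed rf between consecutive contigs.
refine_order <- function(ord, rf) {
  n <- length(ord)
  if (n <= 3L) return(ord)
  path_cost <- function(o) {
    v <- rf[cbind(o[-n], o[-1L])]
    sum(ifelse(is.na(v), 1, v))
  }
  best <- path_cost(ord)
  for (pass in 1:20) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {          # adjacent swaps
      cand <- ord
      cand[c(i, i + 1L)] <- cand[c(i + 1L, i)]
      cc <- path_cost(cand)
      if (cc < best - 1e-12) { ord <- cand; best <- cc; improved <- TRUE }
    }
    for (i in seq_len(n)) {               # single relocations
      for (j in seq_len(n)) {
        if (j == i) next
        cand <- append(ord[-i], ord[i], after = j - 1L)
        cc <- path_cost(cand)
        if (cc < best - 1e-12) { ord <- cand; best <- cc; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  # deterministic orientation: smaller terminal name first
  if (ord[n] < ord[1L]) ord <- rev(ord)
  ord
}

#' Group contigs into linkage groups and order them
#'
#' Grouping proceeds in two stages, mirroring how genetic-map builders
#' combine strong linkage with map linearity:
#'
#' 1. *Strict linkage*: connected components of the graph joining contig
#'    pairs with rf below `rf_strict` (single linkage). At F2 sample sizes
#'    the unlinked lower tail below this threshold is negligible, so these
#'    components are virtually never contaminated.
#' 2. *End joining*: each component is ordered (see below) and components
#'    are then iteratively merged - closest first - when the minimum rf
#'    between their *terminal* contigs is below `rf_link_threshold`. True
#'    fragments of one chromosome join end-to-end; a spurious low rf to an
#'    interior contig of another group cannot cause a merge.
#'
#' Within each group, contigs are ordered by their tree distance from one
#' endpoint of the weighted diameter path of the minimum spanning tree of
#' the rf graph; ties and orientation are resolved lexicographically by
#' contig name, so the output is deterministic. Contigs with zero
#' informative plants become flagged singleton groups.
#'
#' @param codes A `contig_code_table` or genotype matrix
#'   (see [rf_matrix()]).
#' @param rf_link_threshold Maximum rf for an end-to-end join (strict `<`,
#'   default 0.2; the exact unlinked lower tail below 0.2 is about 3e-6
#'   per contig pair at 50 plants - see the methods vignette).
#' @param states Optional `marker_state_table` for the same contigs. When
#'   given, between-contig rf comes from [contig_rf_matrix()]
#'   (closest-marker estimates, which retain plants recombinant within a
#'   contig and are markedly sharper); otherwise the code-level
#'   [rf_matrix()] estimate is used.
#' @param rf_strict Threshold of the strict first stage (default 0.1).
#' @return A `linkage_groups` object: list with `groups` (list of ordered
#'   contig name vectors, one per group, named `LG1`, `LG2`, ... by the
#'   lexicographically smallest member), `membership` (named vector),
#'   `rf` (the full rf matrix) and `flagged_singletons`.
#' @export
group_and_order <- function(codes, rf_link_threshold = 0.2, states = NULL,
                            rf_strict = 0.1) {
  g <- codes_to_genotypes(codes)
  if (nrow(g) < 1L) stop("no contigs to group")
  if (!is.null(states)) {
    est <- contig_rf_matrix(states)
    est$rf <- est$rf[rownames(g), rownames(g)]
  } else {
    est <- rf_matrix(codes)
  }
  rf <- est$rf
  no_info <- rowSums(!is.na(g)) == 0L
  ids <- rownames(g)

  adj <- !is.na(rf) & rf < rf_strict
  diag(adj) <- FALSE
  adj[no_info, ] <- FALSE; adj[, no_info] <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  comps <- lapply(split(ids, comp), order_along_mst, rf = rf)

  # iterative end-to-end joining of components
  terminals <- function(members) {
    if (length(members) <= 2L) members else
      c(members[1L], members[length(members)])
  }
  repeat {
    if (length(comps) < 2L) break
    best <- NULL
    for (i in seq_along(comps)) {
      if (all(comps[[i]] %in% ids[no_info])) next
      for (j in seq_len(i - 1L)) {
        if (all(comps[[j]] %in% ids[no_info])) next
        sub <- rf[terminals(comps[[i]]), terminals(comps[[j]]), drop = FALSE]
        if (all(is.na(sub))) next
        v <- min(sub, na.rm = TRUE)
        if (v < rf_link_threshold && (is.null(best) || v < best$v))
          best <- list(i = i, j = j, v = v)
      }
    }
    if (is.null(best)) break
    merged <- order_along_mst(c(comps[[best$i]], comps[[best$j]]), rf)
    comps <- c(comps[-c(best$i, best$j)], list(merged))
  }

  # deterministic group order: by smallest member name
  comps <- comps[order(vapply(comps, min, character(1)))]
  names(comps) <- paste0("LG", seq_along(comps))

  membership <- stats::setNames(
    rep(names(comps), lengths(comps)), unlist(comps))
  structure(list(groups = comps, membership = membership, rf = rf,
                 flagged_singletons = ids[no_info]),
            class = "linkage_groups")
}

#' Linkage groups as a tidy table
#'
#' @param x A `linkage_groups` object.
#' @return Data frame `group`, `rank`, `contig`.
#' @export
linkage_group_table <- function(x) {
  do.call(rbind, lapply(names(x$groups), function(gname) {
    data.frame(group = gname, rank = seq_along(x$groups[[gname]]),
               contig = x$groups[[gname]], stringsAsFactors = FALSE)
  }))
}

#' Count recombination events per plant along ordered linkage groups
#'
#' Walks each plant's non-missing genotype sequence along the given row
#' order and sums the absolute genotype changes - the observed recombination
#' events on that chromosome in that plant (two meioses). Works on marker
#' states (rows keyed by the state-table row names) or contig codes.
#'
#' @param table A `marker_state_table` or `contig_code_table`.
#' @param group_rows Named list: group id -> ordered vector of row names.
#' @return A `recombination_report`: list with `per_plant` (groups x plants
#'   event matrix), `summary` (data frame `group`, `mean_events`,
#'   `total_events`, `n_plants`).
#' @export
recombinations_per_chromosome <- function(table, group_rows) {
  g <- if (inherits(table, "marker_state_table")) table$states
       else codes_to_genotypes(table)
  per <- t(vapply(group_rows, function(rows) {
    if (anyNA(match(rows, rownames(g))))
      stop("group rows missing from table (unordered or unknown group)")
    sub <- g[rows, , drop = FALSE]
    apply(sub, 2L, function(col) {
      v <- col[!is.na(col)]
      if (length(v) < 2L) return(0)
      sum(abs(diff(v)))
    })
  }, numeric(ncol(g))))
  summary <- data.frame(group = rownames(per),
                        mean_events = rowMeans(per),
                        total_events = rowSums(per),
                        n_plants = ncol(per), stringsAsFactors = FALSE)
  structure(list(per_plant = per, summary = summary),
            class = "recombination_report")
}
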