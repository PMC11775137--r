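#' Family x slice abundance matrix with retention filters
#'
#' Sums reads over lakes and taxa within each family per time-slice, then
#' retains only families with at least `min_reads` total reads across all
#' slices *and* presence in at least `min_slices` slices.
#'
#' @param table Validated occurrence table with a populated `family` column.
#' @param n_slices Number of slices (columns of the matrix).
#' @param min_reads Minimum total reads filter (default 10).
#' @param min_slices Minimum occupied-slice filter (default 5).
#' @return Numeric matrix families x slices with attribute
#'   `"dropped_families"`.
#' @export
aggregate_families <- function(table, n_slices = max(table$slice_index),
                               min_reads = 10, min_slices = 5) {
  if (!nrow(table)) stop("aggregate_families: empty table", call. = FALSE)
  fams <- sort(unique(table$family))
  m <- matrix(0, length(fams), n_slices,
              dimnames = list(fams, as.character(seq_len(n_slices))))
  agg <- rowsum(as.numeric(table$reads),
                paste(table$family, table$slice_index, sep = "\r"))
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  m[cbind(match(vapply(parts, `[`, "", 1L), fams),
          as.integer(vapply(parts, `[`, "", 2L)))] <- agg[, 1]
  keep <- rowSums(m) >= min_reads & rowSums(m > 0) >= min_slices
  if (!any(keep)) {
    stop("aggregate_families: no family passes the filters", call. = FALSE)
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "dropped_families") <- fams[!keep]
  out
}

#' All-pairs Spearman correlations of family abundance series
#'
#' Spearman correlation (average ranks for ties) between every pair of
#' family series across time-slices, with two-sided t-approximation
#' p-values and Benjamini-Hochberg adjustment over the upper triangle.
#' Pairs involving a constant series are `NA`.
#'
#' @param m Family x slice abundance matrix (>= 2 families, >= 4 slices).
#' @return List of symmetric matrices `r`, `p`, `p_adj`.
#' @export
spearman_matrix <- function(m) {
  nf <- nrow(m); ns <- ncol(m)
  if (nf < 2) stop("spearman_matrix: need >= 2 families", call. = FALSE)
  if (ns < 4) stop("spearman_matrix: need >= 4 slices", call. = FALSE)
  rk <- t(apply(m, 1, rank))
  const <- apply(m, 1, function(v) stats::sd(v) == 0)
  r <- stats::cor(t(rk))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- 1
  tstat <- r * sqrt((ns - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), ns - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- NA
  ut <- upper.tri(p)
  p_adj <- matrix(NA_real_, nf, nf, dimnames = dimnames(r))
  p_adj[ut] <- stats::p.adjust(p[ut], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(r = r, p = p, p_adj = p_adj)
}

#' Build the positive co-occurrence network
#'
#' An undirected edge joins two families when their Spearman correlation
#' exceeds `r_threshold` *and* the adjusted p-value is below `alpha`
#' (positive correlations only; strong negative correlations never form
#' edges). Families without any edge remain as isolated degree-0 nodes.
#'
#' @param stats_list Output of [spearman_matrix()].
#' @param r_threshold Minimum correlation (default 0.6).
#' @param alpha Maximum adjusted p (default 0.05).
#' @return Object of class `cooc_network`: list with `graph` (igraph),
#'   `edges` (data frame `family_a`, `family_b`, `r`, `p_adj`) and `nodes`.
#' @export
build_network <- function(stats_list, r_threshold = 0.6, alpha = 0.05) {
  r <- stats_list$r; p_adj <- stats_list$p_adj
  fams <- rownames(r)
  sel <- which(upper.tri(r) & !is.na(r) & !is.na(p_adj) &
                 r > r_threshold & p_adj < alpha, arr.ind = TRUE)
  edges <- data.frame(family_a = fams[sel[, 1]], family_b = fams[sel[, 2]],
                      r = r[sel], p_adj = p_adj[sel],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("family_a", "family_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = fams))
  igraph::E(g)$r <- edges$r
  structure(list(graph = g, edges = edges, nodes = fams,
                 r_threshold = r_threshold, alpha = alpha),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("Positive co-occurrence network:", length(x$nodes), "families,",
      nrow(x$edges), "edges (r >", x$r_threshold, ", adj p <", x$alpha, ")\n")
  invisible(x)
}

#' Detect communities by exact modularity maximisation
#'
#' Finds the node partition maximising Newman-Girvan modularity. For
#' networks with at most `exact_max` non-isolated nodes the optimum is exact
#' (integer-programming search); larger networks fall back to deterministic
#' greedy agglomeration, with the method recorded in the result. Isolated
#' nodes are appended as singleton communities. An edgeless network returns
#' the trivial all-singletons partition with a warning.
#'
#' @param net A [build_network()] object.
#' @param exact_max Largest non-isolated node count for the exact search.
#' @return List of class `community_partition`: `membership` (named integer
#'   vector), `modularity`, `method`.
#' @export
detect_communities <- function(net, exact_max = 16) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  deg <- igraph::degree(g)
  if (sum(deg) == 0) {
    warning("detect_communities: edgeless network, trivial partition",
            call. = FALSE)
    memb <- stats::setNames(seq_along(deg), names(deg))
    return(structure(list(membership = memb, modularity = NA_real_,
                          method = "trivial"), class = "community_partition"))
  }
  core <- igraph::induced_subgraph(g, which(deg > 0))
  n_core <- igraph::vcount(core)
  if (n_core <= exact_max) {
    cl <- igraph::cluster_optimal(core)
    method <- "exact"
  } else {
    cl <- igraph::cluster_fast_greedy(core)
    method <- "greedy"
  }
  memb_core <- igraph::membership(cl)
  memb <- integer(length(deg))
  names(memb) <- names(deg)
  memb[names(memb_core)] <- as.integer(memb_core)
  iso <- which(memb == 0L)
  memb[iso] <- max(memb) + seq_along(iso)
  structure(list(membership = memb,
                 modularity = igraph::modularity(core, memb_core),
                 method = method),
            class = "community_partition")
}

#' Per-community node, edge and link-proportion metrics
#'
#' For each community: its node count, the number of internal edges (both
#' endpoints inside) and the positive link proportion, i.e. internal edges
#' as a percentage of all network edges. (Published figures of this kind can
#' use an unstated denominator; both counts are therefore reported so any
#' ratio can be recomputed.) Per-node degrees are returned for node sizing.
#'
#' @param net A [build_network()] object.
#' @param partition A [detect_communities()] result.
#' @return List with `communities` (data frame `community`, `n_nodes`,
#'   `internal_edges`, `total_edges`, `positive_link_pct`) and `degrees`
#'   (data frame `family`, `degree`, `community`).
#' @export
community_metrics <- function(net, partition) {
  memb <- partition$membership
  deg <- igraph::degree(net$graph)
  e <- net$edges
  total <- nrow(e)
  comm_ids <- sort(unique(memb))
  internal <- vapply(comm_ids, function(cm) {
    sum(memb[e$family_a] == cm & memb[e$family_b] == cm)
  }, numeric(1))
  list(
    communities = data.frame(
      community = comm_ids,
      n_nodes = as.integer(table(memb)[as.character(comm_ids)]),
      internal_edges = as.integer(internal),
      total_edges = total,
      positive_link_pct = if (total > 0) 100 * internal / total else NA_real_
    ),
    degrees = data.frame(family = names(deg), degree = as.integer(deg),
                         community = as.integer(memb[names(deg)]),
                         stringsAsFactors = FALSE)
  )
}

#' Label communities by the climatic regime of their abundance
#'
#' A reporting convenience: each community is labelled `"glacial"` or
#' `"holocene"` according to which regime's slices hold the larger share of
#' the summed abundance of its member families.
#'
#' @param fam_matrix The [aggregate_families()] matrix.
#' @param partition A [detect_communities()] result.
#' @param regime_boundary_slice Slices above this index are glacial.
#' @return Named character vector, one label per community id.
#' @export
label_communities <- function(fam_matrix, partition, regime_boundary_slice = 11) {
  memb <- partition$membership
  slices <- as.integer(colnames(fam_matrix))
  glacial <- slices > regime_boundary_slice
  ids <- sort(unique(memb))
  out <- vapply(ids, function(cm) {
    fams <- intersect(names(memb)[memb == cm], rownames(fam_matrix))
    if (!length(fams)) return(NA_character_)
    tot <- colSums(fam_matrix[fams, , drop = FALSE])
    if (sum(tot[glacial]) >= sum(tot[!glacial])) "glacial" else "holocene"
  }, character(1))
  stats::setNames(out, ids)
}
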