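# Shared fixtures. The default-parameter synthetic run is expensive enough
# to build once and reuse across test files; the cache environment persists
# for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

# Full default-parameter run: simulate, rarefy, summaries (AOO + EOO),
# window analysis, per-iteration classes, abundances.
default_run <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  sim <- generate_community(sim_params(rng_seed = 101))
  cfg <- run_config(rng_seed = 101)
  rs <- rarefy_dataset(sim$occurrence, cfg)
  sm <- slice_range_summaries(rs, sim$lakes, cfg, include_eoo = TRUE)
  wa <- window_analysis(sm, cfg, n_posterior = 200)
  .fixture_cache$default <- list(sim = sim, cfg = cfg, rs = rs, sm = sm,
                                 wa = wa)
  .fixture_cache$default
}

# The four-taxon, seven-lake worked example: taxa A-D spread over lakes in
# slice 1, every sample deep enough that rarefaction keeps it.
toy_occurrence <- function(reads = 6000) {
  occ <- expand.grid(lake_id = sprintf("L%d", 1:7), taxon_id = "A",
                     stringsAsFactors = FALSE)[0, ]
  rows <- list(
    c("L1", "A"), c("L2", "A"), c("L3", "A"),
    c("L2", "B"), c("L4", "B"),
    c("L5", "C"),
    c("L5", "D"), c("L6", "D"), c("L7", "D")
  )
  df <- data.frame(
    lake_id = vapply(rows, `[`, "", 1),
    slice_index = 1L,
    taxon_id = vapply(rows, `[`, "", 2),
    family = "FamX",
    reads = as.integer(reads),
    stringsAsFactors = FALSE
  )
  df
}

toy_lakes <- function() {
  data.frame(lake_id = sprintf("L%d", 1:7),
             lon = c(110, 115, 120, 125, 130, 135, 140),
             lat = c(60, 62, 64, 66, 65, 63, 61),
             stringsAsFactors = FALSE)
}

# Random small presence matrix with at least two non-empty lakes.
random_presence <- function(n_lakes, n_taxa, p = 0.5) {
  repeat {
    m <- matrix(rbinom(n_lakes * n_taxa, 1, p), n_lakes, n_taxa)
    if (sum(rowSums(m) > 0) >= 2 && sum(m) > 0) return(m)
  }
}

# Random undirected graph adjacency with at least one edge.
random_adjacency <- function(n, p = 0.4) {
  repeat {
    a <- matrix(0L, n, n)
    up <- which(upper.tri(a))
    a[up] <- rbinom(length(up), 1, p)
    a <- a + t(a)
    if (sum(a) > 0) return(a)
  }
}

cooc_network_from_adjacency <- function(adj) {
  nf <- nrow(adj)
  fams <- sprintf("F%02d", seq_len(nf))
  dimnames(adj) <- list(fams, fams)
  sel <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(family_a = fams[sel[, 1]], family_b = fams[sel[, 2]],
                      r = rep(0.9, nrow(sel)), p_adj = rep(0.001, nrow(sel)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = fams))
  structure(list(graph = g, edges = edges, nodes = fams,
                 r_threshold = 0.6, alpha = 0.05), class = "cooc_network")
}
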