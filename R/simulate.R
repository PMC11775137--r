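#' Parameters of the synthetic multi-lake community generator
#'
#' The generator emulates a seven-lake, 30-slice (30,000-year) sedaDNA
#' read-count dataset with two climatic regimes. In the "glacial" regime
#' (slices older than the boundary) per-taxon lake occupancy co-varies
#' *positively* with slice richness and cushion-plant families are abundant;
#' in the "Holocene" regime (younger slices) occupancy co-varies *negatively*
#' with richness and tree families are abundant. This is the minimal
#' mechanism that yields the positive-then-negative richness to range-size
#' relationship the analysis is designed to detect.
#'
#' @param n_lakes Number of lakes.
#' @param n_slices Number of 1000-year time-slices (slice 1 most recent).
#' @param regime_boundary_slice Slices `> regime_boundary_slice` are
#'   "glacial", the rest "holocene" (default 11, i.e. a boundary near 11 ka).
#' @param taxon_pool_size Size of the regional taxon pool.
#' @param n_families Number of plant families the pool is divided into.
#' @param n_cushion_families,n_tree_families How many families carry the
#'   cushion / tree growth form; the rest are "other".
#' @param mean_richness Poisson mean of per-slice realized richness
#'   (truncated at 5).
#' @param occupancy_coupling_glacial,occupancy_coupling_holocene Logit-scale
#'   coupling `b` between standardized slice richness and per-taxon lake
#'   occupancy in each regime.
#' @param baseline_occupancy_logit Intercept `a` of the occupancy logit.
#' @param reads_per_lake_slice Sequencing depth of each occupied lake-slice.
#' @param dirichlet_alpha Concentration of the within-sample relative
#'   abundances.
#' @param cushion_weight_glacial,tree_weight_holocene Multiplicative
#'   abundance boost of the favoured group in its regime.
#' @param rng_seed Integer seed of the dataset's RNG stream.
#' @return An object of class `sim_params` (named list).
#' @export
sim_params <- function(n_lakes = 7,
                       n_slices = 30,
                       regime_boundary_slice = 11,
                       taxon_pool_size = 150,
                       n_families = 30,
                       n_cushion_families = 6,
                       n_tree_families = 6,
                       mean_richness = 60,
                       occupancy_coupling_glacial = 0.6,
                       occupancy_coupling_holocene = -0.6,
                       baseline_occupancy_logit = 0,
                       reads_per_lake_slice = 20000,
                       dirichlet_alpha = 1,
                       cushion_weight_glacial = 5,
                       tree_weight_holocene = 5,
                       rng_seed = 1L) {
  p <- as.list(environment())
  counts <- c("n_lakes", "n_slices", "taxon_pool_size", "n_families",
              "mean_richness", "reads_per_lake_slice")
  for (nm in counts) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0) {
      stop("sim_params: '", nm, "' must be positive", call. = FALSE)
    }
  }
  if (p$regime_boundary_slice >= p$n_slices) {
    stop("sim_params: regime_boundary_slice must be < n_slices", call. = FALSE)
  }
  if (p$n_cushion_families + p$n_tree_families > p$n_families) {
    stop("sim_params: more cushion+tree families than families", call. = FALSE)
  }
  if (p$dirichlet_alpha <= 0) stop("sim_params: dirichlet_alpha must be > 0", call. = FALSE)
  class(p) <- "sim_params"
  p
}

#' Generate a synthetic lake registry
#'
#' Draws `n` distinct lake positions uniformly in a lon/lat rectangle.
#'
#' @param n Number of lakes (>= 1).
#' @param bbox Named numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed Integer seed; the same seed yields the same registry.
#' @return A validated lake registry data frame.
#' @export
#' @examples
#' generate_lakes(7, seed = 42)
generate_lakes <- function(n = 7,
                           bbox = c(lon_min = 100, lon_max = 160,
                                    lat_min = 58, lat_max = 72),
                           seed = 1L) {
  if (n < 1) stop("generate_lakes: n must be >= 1", call. = FALSE)
  if (bbox[["lon_max"]] <= bbox[["lon_min"]] ||
      bbox[["lat_max"]] <= bbox[["lat_min"]]) {
    stop("generate_lakes: degenerate bounding box", call. = FALSE)
  }
  with_seed(seed, {
    reg <- data.frame(
      lake_id = sprintf("Lake_%02d", seq_len(n)),
      lon = stats::runif(n, bbox[["lon_min"]], bbox[["lon_max"]]),
      lat = stats::runif(n, bbox[["lat_min"]], bbox[["lat_max"]]),
      stringsAsFactors = FALSE
    )
    validate_lake_registry(reg)
  })
}

# Poisson truncated from below at `lower` by rejection (proper conditional
# distribution; at lambda = 60 the loop essentially never repeats).
rpois_trunc <- function(lambda, lower) {
  repeat {
    s <- stats::rpois(1, lambda)
    if (s >= lower) return(s)
  }
}

#' Generate a synthetic occurrence dataset with known structure
#'
#' Draw order, fixed for reproducibility across versions: for each slice
#' `t = n_slices, ..., 1` (oldest first): (1) richness
#' `S_t ~ Poisson(mean_richness)` truncated at 5; (2) the `S_t` taxa, sampled
#' without replacement from the pool; (3) for each taxon in pool order, its
#' occupied-lake count `L = 1 + Binomial(n_lakes - 1, p_t)` with
#' `logit(p_t) = a + b (S_t - lambda) / sqrt(lambda)` (`b` regime-dependent),
#' then the `L` lakes uniformly without replacement; (4) for each lake in
#' registry order, Dirichlet(`alpha`) relative abundances over the taxa
#' present there (gamma draws), multiplied by the regime's group weight, then
#' a multinomial of `reads_per_lake_slice` reads.
#'
#' The returned truth record is *recounted from the emitted table* (a
#' multinomial draw can assign a present taxon zero reads), so it is exactly
#' consistent with the occurrence rows.
#'
#' @param params A [sim_params()] object.
#' @param lakes A lake registry with `params$n_lakes` rows; default generates
#'   one from `params$rng_seed`.
#' @return An object of class `community_sim`: list with elements
#'   `occurrence` (validated occurrence table), `lakes`, `traits` (family ->
#'   group), `truth` (per-slice richness, regime, per-taxon occupancy counts,
#'   group read fractions) and `params`.
#' @export
generate_community <- function(params = sim_params(), lakes = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(lakes)) lakes <- generate_lakes(params$n_lakes, seed = params$rng_seed)
  lakes <- validate_lake_registry(lakes)
  if (nrow(lakes) != params$n_lakes) {
    stop("generate_community: registry has ", nrow(lakes), " lakes, expected ",
         params$n_lakes, call. = FALSE)
  }

  pool <- sprintf("T%03d", seq_len(params$taxon_pool_size))
  fam_of <- sprintf("Fam%02d", ((seq_len(params$taxon_pool_size) - 1) %%
                                  params$n_families) + 1)
  fams <- sprintf("Fam%02d", seq_len(params$n_families))
  fam_group <- rep("other", params$n_families)
  fam_group[seq_len(params$n_cushion_families)] <- "cushion"
  fam_group[params$n_cushion_families + seq_len(params$n_tree_families)] <- "tree"
  traits <- data.frame(key = fams, group = fam_group, stringsAsFactors = FALSE)
  taxon_group <- fam_group[match(fam_of, fams)]

  lambda <- params$mean_richness
  sd_s <- sqrt(lambda)

  rows <- vector("list", params$n_slices * params$n_lakes)
  truth_rich <- integer(params$n_slices)
  regime <- ifelse(seq_len(params$n_slices) > params$regime_boundary_slice,
                   "glacial", "holocene")
  k <- 0L
  with_seed(params$rng_seed, {
    for (t in seq(params$n_slices, 1L)) {
      s_t <- rpois_trunc(lambda, 5L)
      if (s_t > params$taxon_pool_size) {
        stop("generate_community: realized richness ", s_t,
             " exceeds taxon pool size", call. = FALSE)
      }
      taxa_t <- sort(sample(pool, s_t))
      b <- if (regime[t] == "glacial") params$occupancy_coupling_glacial
           else params$occupancy_coupling_holocene
      p_t <- stats::plogis(params$baseline_occupancy_logit +
                             b * (s_t - lambda) / sd_s)
      # occupancy: membership matrix lakes x present taxa
      occ <- matrix(FALSE, params$n_lakes, s_t)
      for (j in seq_len(s_t)) {
        l_j <- 1L + stats::rbinom(1, params$n_lakes - 1L, p_t)
        occ[sample(params$n_lakes, l_j), j] <- TRUE
      }
      w_group <- c(cushion = 1, tree = 1, other = 1)
      if (regime[t] == "glacial") w_group[["cushion"]] <- params$cushion_weight_glacial
      else w_group[["tree"]] <- params$tree_weight_holocene
      grp_t <- taxon_group[match(taxa_t, pool)]
      for (l in seq_len(params$n_lakes)) {
        present <- which(occ[l, ])
        if (!length(present)) next
        w <- stats::rgamma(length(present), shape = params$dirichlet_alpha) *
          w_group[grp_t[present]]
        reads <- stats::rmultinom(1, params$reads_per_lake_slice, w / sum(w))[, 1]
        pos <- reads > 0
        if (!any(pos)) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          lake_id = lakes$lake_id[l],
          slice_index = t,
          taxon_id = taxa_t[present][pos],
          family = fam_of[match(taxa_t[present][pos], pool)],
          reads = as.integer(reads[pos]),
          stringsAsFactors = FALSE
        )
      }
    }
  })
  occ_table <- validate_occurrence_table(do.call(rbind, rows[seq_len(k)]),
                                         registry = lakes)

  truth <- recount_truth(occ_table, params, regime, traits)
  structure(list(occurrence = occ_table, lakes = lakes, traits = traits,
                 truth = truth, params = params),
            class = "community_sim")
}

# Recount the truth record from an emitted occurrence table so that the two
# are consistent by construction.
recount_truth <- function(occ_table, params, regime, traits) {
  slices <- seq_len(params$n_slices)
  key_ts <- paste(occ_table$taxon_id, occ_table$slice_index, sep = "\r")
  occ_lakes <- rowsum(rep(1L, nrow(occ_table)), key_ts)  # lakes per taxon-slice
  parts <- strsplit(rownames(occ_lakes), "\r", fixed = TRUE)
  occupancy <- data.frame(
    taxon_id = vapply(parts, `[`, "", 1L),
    slice_index = as.integer(vapply(parts, `[`, "", 2L)),
    n_lakes_occupied = as.integer(occ_lakes[, 1]),
    stringsAsFactors = FALSE
  )
  richness <- vapply(slices, function(s) {
    length(unique(occ_table$taxon_id[occ_table$slice_index == s]))
  }, integer(1))
  grp <- resolve_groups(occ_table$taxon_id, occ_table$family, traits)
  total_by_slice <- rowsum(occ_table$reads, occ_table$slice_index)
  frac <- function(g) {
    r <- rowsum(occ_table$reads * (grp == g), occ_table$slice_index)
    as.numeric(r[, 1] / total_by_slice[, 1])
  }
  idx <- match(slices, as.integer(rownames(total_by_slice)))
  list(
    richness = richness,
    regime = regime,
    occupancy = occupancy[order(occupancy$slice_index, occupancy$taxon_id), ],
    group_fraction = data.frame(
      slice_index = slices,
      cushion = frac("cushion")[idx],
      tree = frac("tree")[idx],
      other = frac("other")[idx]
    )
  )
}

#' @export
print.community_sim <- function(x, ...) {
  cat("Synthetic sedaDNA community dataset\n")
  cat("  lakes:", nrow(x$lakes), " slices:", x$params$n_slices,
      " occurrence rows:", nrow(x$occurrence), "\n")
  cat("  regime boundary after slice", x$params$regime_boundary_slice,
      "(older slices glacial)\n")
  invisible(x)
}
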