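#' Per-slice taxonomic richness of one resampling iteration
#'
#' Richness of a time-slice is the number of distinct taxa with at least one
#' rarefied read in *any* lake of that slice.
#'
#' @param rs A [rarefy_dataset()] resample set.
#' @param iteration Iteration index (1-based).
#' @param slice Slice index (1-based).
#' @return Integer richness (0 for an empty slice).
#' @export
richness_per_slice <- function(rs, iteration, slice) {
  m <- rs$counts[, , slice, iteration, drop = FALSE]
  dim(m) <- dim(rs$counts)[1:2]
  sum(colSums(m > 0L) > 0L)
}

#' Per-taxon area of occupancy (occupied-lake counts) in one slice
#'
#' @inheritParams richness_per_slice
#' @return Named integer vector over the taxa present in the slice: the
#'   number of lakes where each has a positive rarefied count.
#' @export
aoo_range <- function(rs, iteration, slice) {
  m <- rs$counts[, , slice, iteration, drop = FALSE]
  dim(m) <- dim(rs$counts)[1:2]
  occ <- colSums(m > 0L)
  stats::setNames(as.integer(occ[occ > 0L]), rs$taxa[occ > 0L])
}

#' Richness and mean range-size for every iteration and slice
#'
#' For each (iteration, slice) cell of the resample set, computes richness
#' `S`, the mean area of occupancy (mean occupied-lake count over the `S`
#' present taxa) and, optionally, the mean extent of occurrence (mean
#' grid-cell hull area, km^2). Slices with `S = 0` carry `NA` means.
#'
#' EOO values are memoised per distinct occupied-lake set: with `L` lakes
#' there are at most `2^L - 1` distinct hulls, so the geometry is computed
#' once per hull regardless of the number of iterations.
#'
#' @param rs A [rarefy_dataset()] resample set.
#' @param lakes Lake registry covering the lakes in `rs` (required for EOO).
#' @param cfg A [run_config()] (grid cell size).
#' @param include_eoo Compute the EOO column? Default `TRUE`.
#' @return Data frame (`iteration`, `slice`, `richness`, `mean_range_aoo`,
#'   `mean_range_eoo`).
#' @export
slice_range_summaries <- function(rs, lakes = NULL, cfg = run_config(),
                                  include_eoo = TRUE) {
  stopifnot(inherits(rs, "resample_set"))
  dm <- dim(rs$counts)
  nl <- dm[1]; nt <- dm[2]; ns <- dm[3]; ni <- dm[4]
  pres <- rs$counts > 0L
  dim(pres) <- c(nl, nt * ns * ni)
  occ <- colSums(pres)                       # lakes occupied per (taxon, slice, iter)
  occ_a <- array(occ, dim = c(nt, ns, ni))
  present <- occ_a > 0L
  richness <- apply(present, c(2, 3), sum)
  aoo_sum <- apply(occ_a, c(2, 3), sum)
  mean_aoo <- ifelse(richness > 0, aoo_sum / richness, NA_real_)

  out <- data.frame(
    iteration = rep(seq_len(ni), each = ns),
    slice = rep(seq_len(ns), ni),
    richness = as.integer(richness),
    mean_range_aoo = as.numeric(mean_aoo),
    mean_range_eoo = NA_real_
  )
  if (include_eoo) {
    if (is.null(lakes)) stop("slice_range_summaries: lakes registry needed for EOO",
                             call. = FALSE)
    if (nl > 30) stop("slice_range_summaries: EOO fast path supports <= 30 lakes",
                      call. = FALSE)
    pr <- project_lakes(lakes)
    pr <- pr[match(rs$lakes, pr$lake_id), ]
    if (anyNA(pr$x)) stop("slice_range_summaries: registry missing lakes",
                          call. = FALSE)
    grid <- make_grid(pr, cfg$grid_cell_km)
    w <- 2^(seq_len(nl) - 1)
    keys <- colSums(pres * w)                # subset key per (taxon, slice, iter)
    uk <- sort(unique(keys[keys > 0]))
    area_of <- vapply(uk, function(k) {
      occ_lakes <- rs$lakes[bitwAnd(as.integer(k), as.integer(w)) > 0]
      eoo_range(occ_lakes, grid, pr)
    }, numeric(1))
    eoo_vals <- rep(0, length(keys))
    pos <- keys > 0
    eoo_vals[pos] <- area_of[match(keys[pos], uk)]
    eoo_a <- array(eoo_vals, dim = c(nt, ns, ni))
    eoo_sum <- apply(eoo_a, c(2, 3), sum)
    out$mean_range_eoo <- as.numeric(ifelse(richness > 0, eoo_sum / richness,
                                            NA_real_))
  }
  out
}

#' Grid-cell richness and range statistics for point occurrences
#'
#' The spatial-domain analogue of the lake pipeline, used for validation
#' against modern occurrence data: points (taxon, lon, lat) are projected
#' into the equal-area frame and binned into grid cells; each taxon's range
#' is its number of occupied cells (AOO in cells), and each cell reports its
#' richness and the mean range of the taxa present in it.
#'
#' @param points Data frame with columns `taxon`, `lon`, `lat`.
#' @param cell_km Grid cell side in kilometres.
#' @return List with `per_taxon` (taxon, range_cells) and `per_cell`
#'   (cell, richness, mean_range_cells).
#' @export
grid_cell_stats <- function(points, cell_km = 200) {
  stopifnot(all(c("taxon", "lon", "lat") %in% names(points)))
  reg <- data.frame(lake_id = sprintf("p%06d", seq_len(nrow(points))),
                    lon = points$lon, lat = points$lat,
                    stringsAsFactors = FALSE)
  pr <- project_lakes(reg)
  grid <- make_grid(pr, cell_km)
  cells <- cell_key(cell_of(grid, pr$x, pr$y))
  occ <- unique(data.frame(taxon = as.character(points$taxon), cell = cells,
                           stringsAsFactors = FALSE))
  rng <- table(occ$taxon)
  per_taxon <- data.frame(taxon = names(rng), range_cells = as.integer(rng),
                          stringsAsFactors = FALSE)
  occ$range <- per_taxon$range_cells[match(occ$taxon, per_taxon$taxon)]
  rich <- table(occ$cell)
  mr <- tapply(occ$range, occ$cell, mean)
  per_cell <- data.frame(cell = names(rich), richness = as.integer(rich),
                         mean_range_cells = as.numeric(mr[names(rich)]),
                         stringsAsFactors = FALSE)
  list(per_taxon = per_taxon, per_cell = per_cell)
}
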