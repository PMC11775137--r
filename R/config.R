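#' Analysis run configuration
#'
#' Collects every tunable parameter of the richness to range-size pipeline in
#' a single validated container. Defaults reproduce the study design the
#' package targets: a 30,000-year multi-lake record binned into 30 slices of
#' 1000 years, rarefied to a base count of 5000 reads with 100 resampling
#' iterations, analysed in 5-slice (5000-year) moving windows, with range
#' sizes on a 200 km equal-area grid.
#'
#' @param slice_width_years Width of one time-slice in calendar years BP.
#' @param n_slices Number of time-slices in the record.
#' @param base_count Rarefaction depth (reads) per lake-slice sample.
#' @param n_iterations Number of rarefaction resampling iterations.
#' @param window_width_slices Number of consecutive slices per moving window.
#' @param window_step_slices Step, in slices, between consecutive windows.
#' @param grid_cell_km Side length of one equal-area grid cell, kilometres.
#' @param r_class_threshold Spearman threshold for classifying a window as a
#'   positive (`R > threshold`) or negative (`R < -threshold`) relationship.
#' @param network_r_threshold Minimum Spearman correlation for a network edge.
#' @param network_alpha Maximum adjusted p-value for a network edge.
#' @param network_min_reads Family filter: minimum total reads over all slices.
#' @param network_min_slices Family filter: minimum number of occupied slices.
#' @param rng_seed Integer seed; every stochastic stage derives its stream
#'   from it.
#'
#' @return An object of class `rrs_config` (a named list).
#' @export
#' @examples
#' cfg <- run_config(n_iterations = 10)
#' cfg$base_count
run_config <- function(slice_width_years = 1000,
                       n_slices = 30,
                       base_count = 5000,
                       n_iterations = 100,
                       window_width_slices = 5,
                       window_step_slices = 1,
                       grid_cell_km = 200,
                       r_class_threshold = 0.2,
                       network_r_threshold = 0.6,
                       network_alpha = 0.05,
                       network_min_reads = 10,
                       network_min_slices = 5,
                       rng_seed = 1L) {
  cfg <- list(
    slice_width_years = slice_width_years,
    n_slices = as.integer(n_slices),
    base_count = as.integer(base_count),
    n_iterations = as.integer(n_iterations),
    window_width_slices = as.integer(window_width_slices),
    window_step_slices = as.integer(window_step_slices),
    grid_cell_km = grid_cell_km,
    r_class_threshold = r_class_threshold,
    network_r_threshold = network_r_threshold,
    network_alpha = network_alpha,
    network_min_reads = network_min_reads,
    network_min_slices = network_min_slices,
    rng_seed = as.integer(rng_seed)
  )
  numeric_fields <- setdiff(names(cfg), "rng_seed")
  for (nm in numeric_fields) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L ||
        !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("run_config: '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (cfg$window_width_slices > cfg$n_slices) {
    stop("run_config: window_width_slices (", cfg$window_width_slices,
         ") exceeds n_slices (", cfg$n_slices, ")", call. = FALSE)
  }
  if (is.na(cfg$rng_seed)) stop("run_config: rng_seed must be an integer", call. = FALSE)
  class(cfg) <- "rrs_config"
  cfg
}

#' @export
print.rrs_config <- function(x, ...) {
  cat("Richness/range-size run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Assign calendar ages to time-slices
#'
#' Slice `k` covers the half-open interval `((k - 1) * width, k * width]`
#' years BP, so slice 1 is the most recent. An age of exactly 0 BP is placed
#' in slice 1.
#'
#' @param age_bp Numeric vector of calendar ages, years BP (non-negative).
#' @param slice_width_years Slice width in years.
#' @return Integer vector of slice indices (1-based).
#' @export
#' @examples
#' age_to_slice(c(0, 1, 1000, 1001, 30000))
age_to_slice <- function(age_bp, slice_width_years = 1000) {
  if (any(!is.finite(age_bp)) || any(age_bp < 0)) {
    stop("age_to_slice: ages must be finite and non-negative", call. = FALSE)
  }
  pmax(1L, as.integer(ceiling(age_bp / slice_width_years)))
}

# Derive a per-iteration seed from the master seed. Kept below 2^31 so the
# value is always a valid R integer.
derive_seed <- function(rng_seed, iteration) {
  as.integer((as.double(rng_seed) * 1000003 + as.double(iteration) * 7919) %%
               2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
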