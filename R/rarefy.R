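#' Rarefy one sample to a fixed read depth
#'
#' Draws `base_count` reads *without replacement* from a vector of taxon read
#' counts (a multivariate hypergeometric draw, realised as a sequence of
#' conditional univariate hypergeometric draws). With
#' `method = "with_replacement"` a multinomial draw is used instead, for
#' sensitivity runs.
#'
#' @param counts Non-negative integer vector of per-taxon read counts.
#' @param base_count Target depth; `sum(counts)` must be at least this.
#' @param method `"without_replacement"` (default) or `"with_replacement"`.
#' @return Integer vector of the same length as `counts`, summing to
#'   `base_count`, element-wise no larger than `counts` (without
#'   replacement).
#' @export
#' @examples
#' set.seed(1)
#' rarefy_sample(c(A = 3000, B = 2500, C = 500), 5000)
rarefy_sample <- function(counts, base_count,
                          method = c("without_replacement", "with_replacement")) {
  method <- match.arg(method)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("rarefy_sample: counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total < base_count) {
    stop("insufficient depth: sample total ", total, " < base count ",
         base_count, call. = FALSE)
  }
  if (method == "with_replacement") {
    out <- stats::rmultinom(1, base_count, counts / total)[, 1]
  } else {
    out <- rarefy_hyper(as.integer(counts), as.integer(base_count))
  }
  names(out) <- names(counts)
  out
}

# Sequential conditional hypergeometric draw; exact multivariate
# hypergeometric without replacement. No validation: internal hot path.
rarefy_hyper <- function(counts, base_count) {
  total <- sum(counts)
  if (total == base_count) return(counts)
  out <- integer(length(counts))
  remaining <- total
  draw <- base_count
  for (j in seq_along(counts)) {
    cj <- counts[j]
    if (cj == 0L) next
    if (draw == 0L) break
    if (draw == remaining) {           # rest must be taken in full
      out[j] <- cj
      draw <- draw - cj
    } else {
      x <- stats::rhyper(1, cj, remaining - cj, draw)
      out[j] <- x
      draw <- draw - x
    }
    remaining <- remaining - cj
  }
  out
}

#' Rarefy a whole occurrence dataset into a resample set
#'
#' Applies [rarefy_sample()] independently to every (lake, slice) sample in
#' every iteration. Samples whose total read count is below `base_count` are
#' excluded identically in all iterations and listed in the exclusion log.
#' Iteration `i` runs under its own RNG substream derived from
#' `(rng_seed, i)`, so a fixed seed gives a bit-identical resample set and
#' iterations are independently reproducible.
#'
#' @param table Validated occurrence table.
#' @param cfg A [run_config()]; uses `base_count`, `n_iterations`,
#'   `n_slices`, `rng_seed`.
#' @return An object of class `resample_set`: list with
#'   \describe{
#'     \item{counts}{integer array `[lake, taxon, slice, iteration]` of
#'       rarefied reads.}
#'     \item{lakes, taxa, slices}{dimension labels.}
#'     \item{retained}{logical matrix `[lake, slice]`.}
#'     \item{exclusions}{data frame of excluded samples and their totals.}
#'   }
#' @export
rarefy_dataset <- function(table, cfg = run_config()) {
  stopifnot(inherits(cfg, "rrs_config"))
  table <- validate_occurrence_table(table)
  if (max(table$slice_index) > cfg$n_slices) {
    stop("rarefy_dataset: table has slice indices beyond cfg$n_slices", call. = FALSE)
  }
  lakes <- sort(unique(table$lake_id))
  taxa <- sort(unique(table$taxon_id))
  nl <- length(lakes); nt <- length(taxa); ns <- cfg$n_slices
  li <- match(table$lake_id, lakes)
  ti <- match(table$taxon_id, taxa)
  si <- table$slice_index

  totals <- matrix(0L, nl, ns)
  tot <- rowsum(table$reads, paste(li, si))
  ks <- strsplit(rownames(tot), " ", fixed = TRUE)
  totals[cbind(as.integer(vapply(ks, `[`, "", 1L)),
               as.integer(vapply(ks, `[`, "", 2L)))] <- as.integer(tot[, 1])
  present <- totals > 0L
  retained <- totals >= cfg$base_count
  excl <- which(present & !retained, arr.ind = TRUE)
  exclusions <- data.frame(lake_id = lakes[excl[, 1]],
                           slice_index = as.integer(excl[, 2]),
                           total_reads = totals[excl],
                           stringsAsFactors = FALSE)
  if (!any(retained)) {
    stop("rarefy_dataset: no sample reaches base count ", cfg$base_count,
         call. = FALSE)
  }

  # per-sample count vectors over their nonzero taxa, once
  keep <- which(retained, arr.ind = TRUE)
  sample_rows <- split(seq_len(nrow(table)), paste(li, si))
  sample_key <- paste(keep[, 1], keep[, 2])
  counts <- array(0L, dim = c(nl, nt, ns, cfg$n_iterations),
                  dimnames = list(lakes, taxa, NULL, NULL))
  plane <- as.double(nl) * nt * ns
  for (it in seq_len(cfg$n_iterations)) {
    with_seed(derive_seed(cfg$rng_seed, it), {
      off <- (it - 1) * plane
      for (s in seq_along(sample_key)) {
        rows <- sample_rows[[sample_key[s]]]
        cv <- table$reads[rows]
        rar <- rarefy_hyper(cv, cfg$base_count)
        idx <- (si[rows][1] - 1L) * (nl * nt) + (ti[rows] - 1L) * nl + li[rows]
        counts[off + idx] <- rar
      }
    })
  }
  structure(list(counts = counts, lakes = lakes, taxa = taxa,
                 slices = seq_len(ns), retained = retained,
                 exclusions = exclusions, base_count = cfg$base_count,
                 n_iterations = cfg$n_iterations, rng_seed = cfg$rng_seed),
            class = "resample_set")
}

#' @export
print.resample_set <- function(x, ...) {
  cat("Rarefaction resample set\n")
  cat("  ", length(x$lakes), "lakes x", length(x$taxa), "taxa x",
      length(x$slices), "slices x", x$n_iterations, "iterations\n")
  cat("  base count:", x$base_count, "; retained samples:",
      sum(x$retained), "; excluded:", nrow(x$exclusions), "\n")
  invisible(x)
}
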