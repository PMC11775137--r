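#' Pairwise incidence components of a lakes x taxa presence matrix
#'
#' For every lake pair (i, j): `a` = taxa shared, `b_ij` = taxa in i but not
#' j, `b_ji` = the reverse, so `a + b_ij` equals the richness of lake i.
#'
#' @param m 0/1 matrix, lakes in rows, taxa in columns; at least two lakes
#'   with at least one taxon.
#' @return Data frame (`i`, `j`, `a`, `b_ij`, `b_ji`) over pairs `i < j`.
#' @export
pairwise_components <- function(m) {
  m <- (m > 0) * 1L
  s <- rowSums(m)
  if (sum(s > 0) < 2) {
    stop("pairwise_components: need at least 2 non-empty lakes", call. = FALSE)
  }
  a <- tcrossprod(m)
  idx <- which(upper.tri(a), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             a = a[idx],
             b_ij = s[idx[, 1]] - a[idx],
             b_ji = s[idx[, 2]] - a[idx])
}

#' Multiple-site Jaccard turnover (replacement) component
#'
#' Baselga's multiple-site Jaccard-family turnover
#' \deqn{\beta_{JTU} = \frac{2\sum_{i<j}\min(b_{ij}, b_{ji})}
#'   {(\sum_i S_i - S_T) + 2\sum_{i<j}\min(b_{ij}, b_{ji})}}
#' where `S_i` are site richnesses and `S_T` the pooled richness. It
#' captures species replacement among sites independently of richness
#' differences (the nestedness part), and is used here as the biotic
#' environmental heterogeneity proxy. With two sites it reduces to the
#' pairwise Jaccard turnover `2 min(b12, b21) / (a + 2 min(b12, b21))`. All
#' sites identical (0/0) is defined as 0.
#'
#' @inheritParams pairwise_components
#' @return `beta_jtu` in \[0, 1\].
#' @export
multisite_jaccard_turnover <- function(m) {
  m <- (m > 0) * 1L
  s <- rowSums(m)
  if (sum(s > 0) < 2) {
    stop("multisite_jaccard_turnover: need at least 2 non-empty lakes",
         call. = FALSE)
  }
  s_t <- sum(colSums(m) > 0)
  a <- tcrossprod(m)
  b <- s - a                     # b[i, j] = taxa in i not in j
  minb <- pmin(b, t(b))
  sum_min <- sum(minb[upper.tri(minb)])
  denom <- (sum(s) - s_t) + 2 * sum_min
  if (denom == 0) return(0)
  2 * sum_min / denom
}

#' Heterogeneity (turnover) series over all iterations and slices
#'
#' Computes [multisite_jaccard_turnover()] on the rarefied presence matrix of
#' every (iteration, slice). Slices with fewer than two occupied lakes yield
#' `NA`; the number of such cells is reported in attribute `"n_skipped"`.
#'
#' @param rs A [rarefy_dataset()] resample set.
#' @return Data frame (`iteration`, `slice`, `beta_jtu`).
#' @export
heterogeneity_series <- function(rs) {
  stopifnot(inherits(rs, "resample_set"))
  dm <- dim(rs$counts)
  ns <- dm[3]; ni <- dm[4]
  out <- expand.grid(slice = seq_len(ns), iteration = seq_len(ni))
  vals <- rep(NA_real_, nrow(out))
  k <- 0L
  for (it in seq_len(ni)) {
    for (s in seq_len(ns)) {
      k <- k + 1L
      m <- rs$counts[, , s, it]
      if (sum(rowSums(m > 0) > 0) >= 2) {
        vals[k] <- multisite_jaccard_turnover(m)
      }
    }
  }
  res <- data.frame(iteration = out$iteration, slice = out$slice,
                    beta_jtu = vals)
  attr(res, "n_skipped") <- sum(is.na(vals))
  res
}
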