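#' Growth-form group relative abundances per iteration and slice
#'
#' The relative abundance of a group in a unit is 100 times its rarefied
#' read count divided by the unit's total reads (read counts are the
#' dataset's unit of observation; set `incidence = TRUE` to use presences
#' instead, for sensitivity runs). Units with zero total reads are `NA`.
#'
#' @param rs A [rarefy_dataset()] resample set.
#' @param traits Trait table mapping taxon ids or families to groups; taxa
#'   without a match count as `"other"`.
#' @param families Character vector giving the family of each taxon in
#'   `rs$taxa` (needed for family-keyed traits); `NULL` if traits are keyed
#'   by taxon id.
#' @param incidence Use presence counts instead of read counts.
#' @return Data frame (`iteration`, `slice`, `cushion_pct`, `tree_pct`).
#' @export
group_abundance <- function(rs, traits, families = NULL, incidence = FALSE) {
  stopifnot(inherits(rs, "resample_set"))
  if (is.null(families)) families <- rep(NA_character_, length(rs$taxa))
  grp <- resolve_groups(rs$taxa, families, traits)
  dm <- dim(rs$counts)
  nl <- dm[1]; nt <- dm[2]; ns <- dm[3]; ni <- dm[4]
  x <- if (incidence) (rs$counts > 0) * 1 else rs$counts
  dim(x) <- c(nl, nt, ns * ni)
  by_taxon <- colSums(x)                      # nt x (ns * ni)
  total <- colSums(by_taxon)
  pct <- function(g) {
    v <- colSums(by_taxon[grp == g, , drop = FALSE])
    ifelse(total > 0, 100 * v / total, NA_real_)
  }
  data.frame(iteration = rep(seq_len(ni), each = ns),
             slice = rep(seq_len(ns), ni),
             cushion_pct = pct("cushion"),
             tree_pct = pct("tree"))
}

#' Median group abundances over moving windows
#'
#' For every (window, iteration): the median of the member slices' group
#' percentages (missing slices dropped), matching the windowed unit of the
#' interaction GLM.
#'
#' @param abund Output of [group_abundance()].
#' @param scheme A [make_windows()] frame.
#' @return Data frame (`window`, `iteration`, `cushion_pct`, `tree_pct`).
#' @export
window_group_abundance <- function(abund, scheme) {
  iters <- sort(unique(abund$iteration))
  ni <- length(iters)
  out <- expand.grid(iteration = iters, window = scheme$window)
  out$cushion_pct <- NA_real_
  out$tree_pct <- NA_real_
  for (w in scheme$window) {
    sl <- window_slices(scheme, w)
    sub <- abund[abund$slice %in% sl, ]
    cu <- tapply(sub$cushion_pct, sub$iteration, stats::median, na.rm = TRUE)
    tr <- tapply(sub$tree_pct, sub$iteration, stats::median, na.rm = TRUE)
    rows <- (w - 1L) * ni + seq_len(ni)
    out$cushion_pct[rows] <- as.numeric(cu[as.character(iters)])
    out$tree_pct[rows] <- as.numeric(tr[as.character(iters)])
  }
  out[, c("window", "iteration", "cushion_pct", "tree_pct")]
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logit fit of a binary response on one predictor (with
#' intercept). Convergence is declared when the largest coefficient change
#' drops below `tol`. Complete separation (a predictor threshold perfectly
#' splitting the classes) and IRLS divergence raise errors rather than
#' returning unbounded estimates.
#'
#' @param y Binary (0/1) response vector with both classes present.
#' @param x Numeric predictor, not constant.
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 50).
#' @return Object of class `logistic_fit`: `coefficients` (intercept,
#'   slope), `se`, `converged`, `iterations`, `loglik`.
#' @export
fit_logistic_irls <- function(y, x, tol = 1e-8, max_iter = 50) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("fit_logistic_irls: y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("fit_logistic_irls: degenerate response, only one class present",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("fit_logistic_irls: predictor is constant", call. = FALSE)
  }
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
    stop("fit_logistic_irls: complete separation, likelihood unbounded",
         call. = FALSE)
  }
  X <- cbind(1, x)
  beta <- c(0, 0)
  loglik <- function(b) {
    eta <- as.vector(X %*% b)
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    xtwx <- crossprod(X, X * w)
    beta_new <- solve(xtwx, crossprod(X, w * z))[, 1]
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (any(abs(beta) > 1e3)) {
      stop("fit_logistic_irls: divergence (quasi-separation suspected)",
           call. = FALSE)
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("fit_logistic_irls: no convergence in ", max_iter, " iterations",
         call. = FALSE)
  }
  p <- stats::plogis(as.vector(X %*% beta))
  w <- p * (1 - p)
  se <- sqrt(diag(solve(crossprod(X, X * w))))
  structure(list(coefficients = stats::setNames(beta, c("intercept", "slope")),
                 se = stats::setNames(se, c("intercept", "slope")),
                 converged = converged, iterations = it,
                 loglik = loglik(beta)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic fit: intercept %.4f (se %.4f), slope %.4f (se %.4f), logLik %.2f\n",
    x$coefficients[1], x$se[1], x$coefficients[2], x$se[2], x$loglik))
  invisible(x)
}

#' Binomial GLMs linking relationship sign to group abundance
#'
#' The paper-level test of the interaction hypothesis: each (window,
#' iteration) unit whose richness to range-size relationship is classified
#' positive (1) or negative (0) — indeterminate units are excluded — is
#' regressed on its cushion-plant and its tree relative abundance in two
#' separate logistic models. Under a facilitation-driven regime shift the
#' cushion slope is positive and the tree slope negative.
#'
#' @param unit_classes Output of [window_iteration_classes()].
#' @param abundances Output of [window_group_abundance()].
#' @return List of class `interaction_fits`: `cushion` and `tree`
#'   [fit_logistic_irls()] objects plus the merged `data`.
#' @export
interaction_analysis <- function(unit_classes, abundances) {
  d <- merge(unit_classes, abundances, by = c("window", "iteration"))
  d <- d[d$class %in% c("positive", "negative") &
           !is.na(d$cushion_pct) & !is.na(d$tree_pct), ]
  if (!nrow(d) || length(unique(d$class)) < 2) {
    stop("interaction_analysis: need both positive and negative units",
         call. = FALSE)
  }
  y <- as.numeric(d$class == "positive")
  structure(list(cushion = fit_logistic_irls(y, d$cushion_pct),
                 tree = fit_logistic_irls(y, d$tree_pct),
                 data = d),
            class = "interaction_fits")
}

#' @export
print.interaction_fits <- function(x, ...) {
  cat("Interaction GLMs (response: 1 = positive relationship)\n")
  cat(sprintf("  cushion abundance: slope %+.4f (se %.4f)\n",
              x$cushion$coefficients[2], x$cushion$se[2]))
  cat(sprintf("  tree abundance:    slope %+.4f (se %.4f)\n",
              x$tree$coefficients[2], x$tree$se[2]))
  cat("  units:", nrow(x$data), "\n")
  invisible(x)
}
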