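#' Build the moving time-window scheme
#'
#' Windows are runs of `width` consecutive slices advancing by `step`,
#' giving `floor((n_slices - width) / step) + 1` windows. Labels give the
#' oldest and youngest bounding ages, e.g. slices 19..23 with 1000-year
#' slices are labelled `"23-19ka"`.
#'
#' @param n_slices Number of slices in the record.
#' @param width Window width in slices (default 5).
#' @param step Step in slices (default 1).
#' @param slice_width_years Slice width, for the age labels.
#' @return Data frame (`window`, `first_slice`, `last_slice`, `label`) of
#'   class `slice_windows`; `window_slices()` recovers the member indices.
#' @export
#' @examples
#' w <- make_windows(30)
#' nrow(w)      # 26
#' w$label[w$first_slice == 19]
make_windows <- function(n_slices, width = 5, step = 1,
                         slice_width_years = 1000) {
  if (width > n_slices) {
    stop("make_windows: width (", width, ") exceeds n_slices (", n_slices, ")",
         call. = FALSE)
  }
  if (width < 1 || step < 1) stop("make_windows: width and step must be >= 1",
                                  call. = FALSE)
  first <- seq(1L, n_slices - width + 1L, by = step)
  last <- first + width - 1L
  ka <- function(s) formatC(s * slice_width_years / 1000, format = "g")
  out <- data.frame(window = seq_along(first), first_slice = first,
                    last_slice = last,
                    label = sprintf("%s–%ska", ka(last), ka(first)),
                    stringsAsFactors = FALSE)
  class(out) <- c("slice_windows", "data.frame")
  out
}

#' @rdname make_windows
#' @param windows A `slice_windows` data frame.
#' @param i Window number.
#' @return `window_slices()`: integer vector of member slice indices.
#' @export
window_slices <- function(windows, i) {
  seq(windows$first_slice[i], windows$last_slice[i])
}

#' Pooled (richness, mean range-size) points of one window
#'
#' One point per (iteration, member slice) with a defined mean range-size;
#' empty slices (richness 0) contribute nothing.
#'
#' @param summaries Output of [slice_range_summaries()].
#' @param slices Integer vector of member slice indices.
#' @param metric `"aoo"` or `"eoo"`: which mean range-size column to use.
#' @return Data frame (`iteration`, `slice`, `richness`, `range`).
#' @export
window_points <- function(summaries, slices, metric = c("aoo", "eoo")) {
  metric <- match.arg(metric)
  col <- paste0("mean_range_", metric)
  sel <- summaries$slice %in% slices & summaries$richness > 0 &
    !is.na(summaries[[col]])
  if (!any(sel)) stop("window_points: window has no data points", call. = FALSE)
  data.frame(iteration = summaries$iteration[sel],
             slice = summaries$slice[sel],
             richness = summaries$richness[sel],
             range = summaries[[col]][sel])
}

#' Ordinary least-squares fit of richness on mean range-size
#'
#' Fits `richness = b0 + b1 * range` by OLS via the QR decomposition,
#' reporting the residual standard deviation `sigma` (`RSS / (n - 2)` under
#' the root) and the coefficient covariance `sigma^2 (X'X)^{-1}`.
#'
#' @param points Data frame with columns `range` (predictor) and `richness`
#'   (response), at least 3 rows.
#' @return An object of class `ols_fit`: list with `coefficients`
#'   (`intercept`, `slope`), `sigma`, `cov`, `r_squared`, `n`, `df`,
#'   `xtx_inv`.
#' @export
fit_linear <- function(points) {
  x <- points$range; y <- points$richness
  n <- length(x)
  if (n < 3) stop("fit_linear: need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("fit_linear: singular fit, predictor is constant", call. = FALSE)
  }
  X <- cbind(intercept = 1, slope = x)
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  df <- n - 2L
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrX))
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = beta, sigma = sqrt(sigma2),
                 cov = sigma2 * xtx_inv, r_squared = 1 - rss / tss,
                 n = n, df = df, xtx_inv = xtx_inv),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit richness ~ mean range-size\n")
  cat(sprintf("  intercept %.4f  slope %.4f  sigma %.4f  R^2 %.3f  n %d\n",
              x$coefficients[1], x$coefficients[2], x$sigma, x$r_squared, x$n))
  invisible(x)
}

#' Posterior simulation of regression coefficients
#'
#' Simulates from the classical Bayesian posterior of the normal linear
#' model with a noninformative prior: per draw,
#' `sigma^2 = sigma_hat^2 * df / chisq(df)` and coefficients from
#' `Normal(beta_hat, sigma^2 (X'X)^{-1})`. A zero residual standard
#' deviation (exactly collinear input) returns the point estimate for every
#' draw.
#'
#' @param fit An [fit_linear()] object.
#' @param n_draws Number of posterior draws (>= 1).
#' @param seed Optional integer seed for a reproducible draw vector.
#' @return Numeric vector of `n_draws` slope draws.
#' @export
posterior_sim <- function(fit, n_draws, seed = NULL) {
  stopifnot(inherits(fit, "ols_fit"))
  if (n_draws < 1) stop("posterior_sim: n_draws must be >= 1", call. = FALSE)
  if (fit$sigma == 0) return(rep(unname(fit$coefficients[2]), n_draws))
  draw <- function() {
    sig <- fit$sigma * sqrt(fit$df / stats::rchisq(n_draws, fit$df))
    z <- matrix(stats::rnorm(2 * n_draws), n_draws, 2)
    ch <- chol(fit$xtx_inv)
    sweep(z %*% ch, 1, sig, `*`)[, 2] + fit$coefficients[2]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Spearman rank correlation with a t-based p-value
#'
#' Average ranks for ties; two-sided p from
#' `t = R sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees of freedom, with
#' `p = 0` when `R = +/-1`.
#'
#' @param x,y Numeric vectors of equal length, at least 4.
#' @return List with elements `R` and `p`.
#' @export
spearman_rp <- function(x, y) {
  n <- length(x)
  if (n < 4) stop("spearman_rp: need at least 4 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman_rp: correlation undefined for a constant variable",
         call. = FALSE)
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1 - 1e-12) return(list(R = sign(r), p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(R = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Classify a richness to range-size relationship by its Spearman R
#'
#' `"positive"` when `R > threshold`, `"negative"` when `R < -threshold`,
#' otherwise `"indeterminate"` (strict inequalities; `R = threshold` is
#' indeterminate). Indeterminate windows are excluded from the interaction
#' GLM.
#'
#' @param R Spearman correlation(s) in \[-1, 1\].
#' @param threshold Classification threshold (default 0.2).
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_relationship(c(0.5, -0.5, 0.2))
classify_relationship <- function(R, threshold = 0.2) {
  if (any(!is.na(R) & (R < -1 | R > 1))) {
    stop("classify_relationship: R outside [-1, 1]", call. = FALSE)
  }
  ifelse(is.na(R), NA_character_,
         ifelse(R > threshold, "positive",
                ifelse(R < -threshold, "negative", "indeterminate")))
}

#' Moving-window regression analysis of the richness to range-size relation
#'
#' For every window: pools the (iteration, slice) points, fits the OLS
#' regression, draws posterior slopes, computes the Spearman correlation and
#' classifies the relationship sign.
#'
#' @param summaries Output of [slice_range_summaries()].
#' @param cfg A [run_config()].
#' @param metric `"aoo"` or `"eoo"` range metric.
#' @param n_posterior Posterior slope draws per window.
#' @return List of class `window_analysis`: `windows` (per-window data frame
#'   with `label`, `n`, `slope`, `intercept`, `sigma`, `spearman_R`, `p`,
#'   `class`), `draws` (matrix `n_posterior` x windows) and `scheme` (the
#'   [make_windows()] frame).
#' @export
window_analysis <- function(summaries, cfg = run_config(),
                            metric = c("aoo", "eoo"), n_posterior = 1000) {
  metric <- match.arg(metric)
  scheme <- make_windows(cfg$n_slices, cfg$window_width_slices,
                         cfg$window_step_slices, cfg$slice_width_years)
  nw <- nrow(scheme)
  res <- data.frame(window = scheme$window, label = scheme$label,
                    first_slice = scheme$first_slice,
                    last_slice = scheme$last_slice,
                    n = NA_integer_, slope = NA_real_, intercept = NA_real_,
                    sigma = NA_real_, spearman_R = NA_real_, p = NA_real_,
                    class = NA_character_, stringsAsFactors = FALSE)
  draws <- matrix(NA_real_, n_posterior, nw, dimnames = list(NULL, scheme$label))
  for (i in seq_len(nw)) {
    pts <- tryCatch(window_points(summaries, window_slices(scheme, i), metric),
                    error = function(e) NULL)
    if (is.null(pts) || nrow(pts) < 4) next
    res$n[i] <- nrow(pts)
    fit <- tryCatch(fit_linear(pts), error = function(e) NULL)
    if (!is.null(fit)) {
      res$slope[i] <- fit$coefficients[2]
      res$intercept[i] <- fit$coefficients[1]
      res$sigma[i] <- fit$sigma
      draws[, i] <- posterior_sim(fit, n_posterior,
                                  seed = derive_seed(cfg$rng_seed, 10000 + i))
    }
    sp <- tryCatch(spearman_rp(pts$range, pts$richness),
                   error = function(e) NULL)
    if (!is.null(sp)) {
      res$spearman_R[i] <- sp$R
      res$p[i] <- sp$p
      res$class[i] <- classify_relationship(sp$R, cfg$r_class_threshold)
    }
  }
  structure(list(windows = res, draws = draws, scheme = scheme,
                 metric = metric), class = "window_analysis")
}

#' Per-iteration window classification
#'
#' The finer-grained unit used by the interaction GLM: for every (window,
#' iteration) pair, the Spearman correlation over that iteration's member
#' slice points and its sign class. Pairs with fewer than 4 usable points or
#' a constant variable are `NA`.
#'
#' @inheritParams window_analysis
#' @return Data frame (`window`, `label`, `iteration`, `R`, `class`).
#' @export
window_iteration_classes <- function(summaries, cfg = run_config(),
                                     metric = c("aoo", "eoo")) {
  metric <- match.arg(metric)
  scheme <- make_windows(cfg$n_slices, cfg$window_width_slices,
                         cfg$window_step_slices, cfg$slice_width_years)
  col <- paste0("mean_range_", metric)
  iters <- sort(unique(summaries$iteration))
  grid <- expand.grid(iteration = iters, window = scheme$window)
  rvals <- rep(NA_real_, nrow(grid))
  by_iter <- split(summaries, summaries$iteration)
  ni <- length(iters)
  for (w in scheme$window) {
    sl <- window_slices(scheme, w)
    for (j in seq_along(iters)) {
      k <- (w - 1L) * ni + j
      s <- by_iter[[j]]
      sel <- s$slice %in% sl & s$richness > 0 & !is.na(s[[col]])
      if (sum(sel) >= 4) {
        sp <- tryCatch(spearman_rp(s[[col]][sel], s$richness[sel]),
                       error = function(e) NULL)
        if (!is.null(sp)) rvals[k] <- sp$R
      }
    }
  }
  data.frame(window = grid$window,
             label = scheme$label[grid$window],
             iteration = grid$iteration,
             R = rvals,
             class = classify_relationship(rvals, cfg$r_class_threshold),
             stringsAsFactors = FALSE)
}
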