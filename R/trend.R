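#' Fit the temporal richness to range-size trend of a multi-lake record
#'
#' The package's central estimator. Starting from a long-format occurrence
#' table, it (1) rarefies every lake-slice sample to a common read depth
#' over `n_iterations` resampling iterations, (2) computes per-slice
#' richness and mean range-size (occupied-lake AOO and, optionally,
#' grid-cell-hull EOO), (3) fits the richness ~ mean range-size regression
#' in moving 5-slice windows with posterior slope draws, Spearman
#' correlation and a sign classification, (4) measures biotic heterogeneity
#' as multiple-site Jaccard turnover per slice, and — when a trait table is
#' given — (5) fits the two binomial GLMs linking the per-window-iteration
#' relationship sign to cushion-plant and tree relative abundance, and (6)
#' builds the family-level positive co-occurrence network with exact
#' modularity communities.
#'
#' @param occurrence Occurrence table (see [read_occurrence_table()]), or a
#'   [generate_community()] object (in which case `lakes` and `traits`
#'   default to its own).
#' @param lakes Lake registry data frame.
#' @param traits Optional trait table; `NULL` skips stages (5)-(6)'s GLMs.
#' @param config A [run_config()].
#' @param metric Range-size metric driving the windows: `"aoo"` (default,
#'   occupied-lake counts) or `"eoo"` (grid-hull area, km^2).
#' @param include_eoo Also compute the EOO summary column (default `TRUE`;
#'   forced on when `metric = "eoo"`).
#' @param network Build the co-occurrence network (default `TRUE`).
#' @param n_posterior Posterior slope draws per window.
#' @param regime_boundary_slice Used only to label network communities;
#'   `NULL` skips labelling.
#' @return An object of class `rrs_trend` with components `summaries`,
#'   `windows` (a [window_analysis()] result), `heterogeneity`,
#'   `abundance`, `unit_classes`, `glm` (an [interaction_analysis()] result
#'   or `NULL`), `network`, `communities`, `community_metrics`,
#'   `community_labels`, `resamples`, `config`, `call`. Methods: `print`,
#'   `summary`, `coef` (window slopes), `plot`.
#' @export
#' @examples
#' sim <- generate_community(sim_params(rng_seed = 7))
#' cfg <- run_config(n_iterations = 5, rng_seed = 7)
#' fit <- range_size_trend(sim, config = cfg, include_eoo = FALSE,
#'                         network = FALSE, n_posterior = 100)
#' print(fit)
#' head(coef(fit))
range_size_trend <- function(occurrence, lakes = NULL, traits = NULL,
                             config = run_config(),
                             metric = c("aoo", "eoo"),
                             include_eoo = TRUE, network = TRUE,
                             n_posterior = 1000,
                             regime_boundary_slice = NULL) {
  metric <- match.arg(metric)
  cl <- match.call()
  if (inherits(occurrence, "community_sim")) {
    if (is.null(lakes)) lakes <- occurrence$lakes
    if (is.null(traits)) traits <- occurrence$traits
    if (is.null(regime_boundary_slice)) {
      regime_boundary_slice <- occurrence$params$regime_boundary_slice
    }
    occurrence <- occurrence$occurrence
  }
  if (is.null(lakes)) stop("range_size_trend: a lake registry is required",
                           call. = FALSE)
  occurrence <- validate_occurrence_table(occurrence, registry = lakes)
  if (metric == "eoo") include_eoo <- TRUE

  rs <- rarefy_dataset(occurrence, config)
  summaries <- slice_range_summaries(rs, lakes = if (include_eoo) lakes,
                                     cfg = config, include_eoo = include_eoo)
  wins <- window_analysis(summaries, config, metric = metric,
                          n_posterior = n_posterior)
  het <- heterogeneity_series(rs)

  abund <- unit_classes <- glm_fits <- NULL
  families <- occurrence$family[match(rs$taxa, occurrence$taxon_id)]
  if (!is.null(traits)) {
    traits <- validate_trait_table(traits)
    abund_slice <- group_abundance(rs, traits, families = families)
    abund <- window_group_abundance(abund_slice, wins$scheme)
    unit_classes <- window_iteration_classes(summaries, config, metric = metric)
    glm_fits <- tryCatch(interaction_analysis(unit_classes, abund),
                         error = function(e) {
                           warning("interaction GLM skipped: ",
                                   conditionMessage(e), call. = FALSE)
                           NULL
                         })
    attr(abund, "slice_level") <- abund_slice
  }

  net <- comm <- cm <- labels <- NULL
  if (network) {
    net <- tryCatch({
      fm <- aggregate_families(occurrence, n_slices = config$n_slices,
                               min_reads = config$network_min_reads,
                               min_slices = config$network_min_slices)
      st <- spearman_matrix(fm)
      n <- build_network(st, config$network_r_threshold, config$network_alpha)
      attr(n, "family_matrix") <- fm
      n
    }, error = function(e) {
      warning("network stage skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(net)) {
      comm <- suppressWarnings(detect_communities(net))
      cm <- community_metrics(net, comm)
      if (!is.null(regime_boundary_slice)) {
        labels <- label_communities(attr(net, "family_matrix"), comm,
                                    regime_boundary_slice)
      }
    }
  }

  structure(list(summaries = summaries, windows = wins, heterogeneity = het,
                 abundance = abund, unit_classes = unit_classes,
                 glm = glm_fits, network = net, communities = comm,
                 community_metrics = cm, community_labels = labels,
                 resamples = rs, config = config, metric = metric, call = cl),
            class = "rrs_trend")
}

#' @export
print.rrs_trend <- function(x, ...) {
  w <- x$windows$windows
  cat("Temporal richness to range-size trend (", x$metric, " range metric)\n",
      sep = "")
  cat("  ", length(x$resamples$lakes), "lakes,", length(x$resamples$slices),
      "slices,", x$resamples$n_iterations, "rarefaction iterations (base",
      x$resamples$base_count, "reads)\n")
  tb <- table(factor(w$class, levels = c("positive", "negative",
                                         "indeterminate")))
  cat("  windows:", nrow(w), "->", tb[["positive"]], "positive,",
      tb[["negative"]], "negative,", tb[["indeterminate"]], "indeterminate\n")
  if (!is.null(x$glm)) {
    cat(sprintf("  interaction GLM slopes: cushion %+.3f, tree %+.3f\n",
                x$glm$cushion$coefficients[2], x$glm$tree$coefficients[2]))
  }
  if (!is.null(x$network)) {
    cat("  network:", length(x$network$nodes), "families,",
        nrow(x$network$edges), "edges,",
        length(unique(x$communities$membership[
          names(igraph::degree(x$network$graph))[
            igraph::degree(x$network$graph) > 0]])),
        "communities among linked nodes\n")
  }
  invisible(x)
}

#' @export
summary.rrs_trend <- function(object, ...) {
  out <- list(windows = object$windows$windows,
              glm = object$glm,
              communities = object$community_metrics,
              labels = object$community_labels,
              exclusions = object$resamples$exclusions)
  class(out) <- "summary.rrs_trend"
  out
}

#' @export
print.summary.rrs_trend <- function(x, ...) {
  cat("Per-window richness ~ mean range-size fits:\n")
  print(x$windows, row.names = FALSE, digits = 3)
  if (!is.null(x$glm)) { cat("\n"); print(x$glm) }
  if (!is.null(x$communities)) {
    cat("\nNetwork communities:\n")
    df <- x$communities$communities
    if (!is.null(x$labels)) df$regime <- x$labels[as.character(df$community)]
    print(df, row.names = FALSE, digits = 4)
  }
  if (nrow(x$exclusions)) {
    cat("\nSamples excluded at rarefaction:", nrow(x$exclusions), "\n")
  }
  invisible(x)
}

#' @export
coef.rrs_trend <- function(object, ...) {
  w <- object$windows$windows
  stats::setNames(w$slope, w$label)
}

#' Plot the fitted temporal trend
#'
#' Base-graphics panels over window age: (1) median richness, (2) median
#' mean range-size, (3) posterior slope distributions (boxes), (4) median
#' turnover heterogeneity, and, when available, (5) cushion and tree
#' abundance medians.
#'
#' @param x An `rrs_trend` object.
#' @param which Panels to draw (subset of 1:5).
#' @param ... Unused.
#' @export
plot.rrs_trend <- function(x, which = 1:5, ...) {
  w <- x$windows$windows
  scheme <- x$windows$scheme
  age <- (scheme$first_slice + scheme$last_slice) / 2 *
    x$config$slice_width_years / 1000
  sm <- x$summaries
  med_by_window <- function(col) {
    vapply(seq_len(nrow(scheme)), function(i) {
      v <- sm[[col]][sm$slice %in% window_slices(scheme, i)]
      stats::median(v, na.rm = TRUE)
    }, numeric(1))
  }
  panels <- intersect(which, 1:5)
  if (is.null(x$abundance)) panels <- setdiff(panels, 5)
  op <- graphics::par(mfrow = c(length(panels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  if (1 %in% panels) {
    graphics::plot(age, med_by_window("richness"), type = "b", pch = 16,
                   xlim = rev(range(age)), xlab = "", ylab = "richness")
  }
  if (2 %in% panels) {
    col <- paste0("mean_range_", x$metric)
    graphics::plot(age, med_by_window(col), type = "b", pch = 16,
                   xlim = rev(range(age)), xlab = "",
                   ylab = paste("mean range (", x$metric, ")"))
  }
  if (3 %in% panels) {
    draws <- x$windows$draws[, rev(seq_len(ncol(x$windows$draws)))]
    # plain hyphens: not every graphics device encodes the en dash
    colnames(draws) <- gsub("–", "-", colnames(draws))
    graphics::boxplot(draws, outline = FALSE, las = 2, cex.axis = 0.5,
                      ylab = "posterior slope")
    graphics::abline(h = 0, lty = 2)
  }
  if (4 %in% panels) {
    het <- merge(x$heterogeneity,
                 data.frame(slice = sm$slice, iteration = sm$iteration))
    hw <- vapply(seq_len(nrow(scheme)), function(i) {
      stats::median(x$heterogeneity$beta_jtu[
        x$heterogeneity$slice %in% window_slices(scheme, i)], na.rm = TRUE)
    }, numeric(1))
    graphics::plot(age, hw, type = "b", pch = 16, xlim = rev(range(age)),
                   xlab = "", ylab = "turnover (beta_jtu)")
  }
  if (5 %in% panels) {
    cu <- vapply(seq_len(nrow(scheme)), function(i) {
      stats::median(x$abundance$cushion_pct[x$abundance$window == i],
                    na.rm = TRUE)
    }, numeric(1))
    tr <- vapply(seq_len(nrow(scheme)), function(i) {
      stats::median(x$abundance$tree_pct[x$abundance$window == i],
                    na.rm = TRUE)
    }, numeric(1))
    graphics::plot(age, cu, type = "b", pch = 16, xlim = rev(range(age)),
                   ylim = range(c(cu, tr), na.rm = TRUE),
                   xlab = "window mid-age (ka BP)", ylab = "abundance (%)")
    graphics::lines(age, tr, type = "b", pch = 1)
    graphics::legend("top", c("cushion", "tree"), pch = c(16, 1), bty = "n",
                     horiz = TRUE)
  }
  invisible(x)
}
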