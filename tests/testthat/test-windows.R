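test_that("window construction counts, labels and membership are exact", {
  w <- make_windows(30, 5, 1)
  expect_equal(nrow(w), 26)
  expect_equal(window_slices(w, 1), 1:5)
  # slices 19..23 span 23 ka down to 19 ka
  i <- which(w$first_slice == 19)
  expect_equal(w$label[i], "23–19ka")
  expect_equal(w$label[i - 1], "22–18ka")
  expect_equal(nrow(make_windows(30, 30)), 1)
  expect_error(make_windows(4, 5), "exceeds n_slices")
})

test_that("window points pool (iteration, slice) pairs with defined means", {
  # 5 slices x 100 iterations, all present -> 500 points
  sm <- expand.grid(iteration = 1:100, slice = 1:6)
  sm$richness <- 10L
  sm$mean_range_aoo <- 3
  pts <- window_points(sm, 1:5)
  expect_equal(nrow(pts), 500)
  # a slice empty in every iteration drops its 100 points
  sm$richness[sm$slice == 3] <- 0L
  expect_equal(nrow(window_points(sm, 1:5)), 400)
  sm$richness <- 0L
  expect_error(window_points(sm, 1:5), "no data points")
})

test_that("the OLS fit matches interpolation, symmetry and the normal equations", {
  pts <- data.frame(range = 1:10, richness = 2 * (1:10) + 1)
  fit <- fit_linear(pts)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-6)

  cross <- data.frame(range = c(0, 0, -1, 1), richness = c(-1, 1, 0, 0))
  expect_equal(unname(fit_linear(cross)$coefficients[2]), 0, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:20) {
    x <- runif(50); y <- 3 + 0.5 * x + rnorm(50)
    fit <- fit_linear(data.frame(range = x, richness = y))
    or <- oracle_ols(x, y)
    expect_equal(unname(fit$coefficients), or$coef, tolerance = 1e-10)
    expect_equal(fit$sigma, or$sigma, tolerance = 1e-10)
  }
  expect_error(fit_linear(data.frame(range = rep(1, 5), richness = 1:5)),
               "singular")
  expect_error(fit_linear(pts[1:2, ]), "at least 3")
})

test_that("posterior slope simulation is unbiased and seed-stable", {
  pts <- data.frame(range = 1:10, richness = 2 * (1:10) + 1)
  expect_equal(posterior_sim(fit_linear(pts), 50), rep(2, 50), tolerance = 1e-6)

  set.seed(8)
  x <- runif(40); y <- 1 + 2 * x + rnorm(40, sd = 0.5)
  fit <- fit_linear(data.frame(range = x, richness = y))
  draws <- posterior_sim(fit, 1e4, seed = 99)
  # MC standard error of the draw mean
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - fit$coefficients[2]), 3 * se)
  expect_identical(draws, posterior_sim(fit, 1e4, seed = 99))
  expect_error(posterior_sim(fit, 0), "n_draws")
})

test_that("Spearman correlation handles monotone, tied and transformed data", {
  expect_equal(spearman_rp(1:8, (1:8)^3)$R, 1)
  expect_equal(spearman_rp(1:8, (1:8)^3)$p, 0)
  expect_equal(spearman_rp(1:8, -(1:8))$R, -1)

  # tied example against explicit average-rank arithmetic
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  rx <- c(1, 2.5, 2.5, 4, 5, 6.5, 6.5, 8)
  ry <- c(2, 1, 3.5, 3.5, 6, 5, 7.5, 7.5)
  r_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  sp <- spearman_rp(x, y)
  expect_equal(sp$R, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(6 / (1 - r_hand^2))
  expect_equal(sp$p, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  # agrees with the standard estimator
  expect_equal(sp$R, unname(cor(x, y, method = "spearman")), tolerance = 1e-12)

  # invariant under strictly monotone transforms of either axis
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_rp(exp(a), b)$R, spearman_rp(a, b)$R)
  expect_equal(spearman_rp(a, qlogis(plogis(b)))$R, spearman_rp(a, b)$R)

  expect_error(spearman_rp(rep(1, 6), 1:6), "constant")
  expect_error(spearman_rp(1:3, 3:1), "at least 4")
})

test_that("relationship classification applies strict thresholds", {
  expect_equal(classify_relationship(c(0.5, -0.5, 0.2, -0.2, 0)),
               c("positive", "negative", "indeterminate", "indeterminate",
                 "indeterminate"))
  expect_error(classify_relationship(1.2), "outside")
})

test_that("window analysis ties fits, draws and classes together", {
  run <- default_run()
  w <- run$wa$windows
  expect_equal(nrow(w), 26)
  expect_true(all(w$n == 500))
  # class consistent with R and threshold in every window
  expect_equal(w$class, classify_relationship(w$spearman_R, 0.2))
  # posterior draw matrix aligned with windows
  expect_equal(dim(run$wa$draws), c(200, 26))
  # glacial windows positive, holocene negative on the default generator
  expect_true(all(w$class[w$first_slice >= 12] == "positive"))
  expect_true(all(w$class[w$last_slice <= 11] == "negative"))
})
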