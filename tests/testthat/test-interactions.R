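# Minimal hand-built resample set: 1 lake, 3 taxa, 2 slices, 1 iteration.
tiny_resamples <- function(counts_slice1, counts_slice2,
                           taxa = c("t1", "t2", "t3")) {
  counts <- array(0L, dim = c(1, 3, 2, 1),
                  dimnames = list("L1", taxa, NULL, NULL))
  counts[1, , 1, 1] <- counts_slice1
  counts[1, , 2, 1] <- counts_slice2
  structure(list(counts = counts, lakes = "L1", taxa = taxa, slices = 1:2,
                 retained = matrix(TRUE, 1, 2),
                 exclusions = data.frame(), base_count = sum(counts_slice1),
                 n_iterations = 1L, rng_seed = 1L),
            class = "resample_set")
}

test_that("group abundance is the read share of each growth form", {
  traits <- data.frame(key = c("t1", "t2"), group = c("cushion", "tree"))
  rs <- tiny_resamples(c(12L, 0L, 0L), c(3L, 0L, 9L))
  ab <- group_abundance(rs, traits)
  expect_equal(ab$cushion_pct, c(100, 25))   # all reads / 3 of 12 reads
  expect_equal(ab$tree_pct, c(0, 0))
  # taxa without a trait match count as "other"
  rs2 <- tiny_resamples(c(4L, 4L, 4L), c(0L, 6L, 6L))
  ab2 <- group_abundance(rs2, traits)
  expect_equal(ab2$cushion_pct, c(100 / 3, 0))
  expect_equal(ab2$tree_pct, c(100 / 3, 50))
})

test_that("windowed abundances take per-iteration medians over member slices", {
  abund <- data.frame(iteration = rep(1:2, each = 3),
                      slice = rep(1:3, 2),
                      cushion_pct = c(10, 20, 60, 10, 30, 50),
                      tree_pct = 0)
  scheme <- make_windows(3, 3)
  w <- window_group_abundance(abund, scheme)
  expect_equal(w$cushion_pct, c(20, 30))
})

test_that("logistic IRLS matches the likelihood-grid oracle", {
  set.seed(4)
  # zero-slope truth: intercept recovers logit of the base rate
  y <- rbinom(200, 1, 0.6)
  x <- rnorm(200)
  fit <- fit_logistic_irls(y, x)
  or <- oracle_logistic_grid(y, x)
  expect_equal(unname(fit$coefficients), unname(or), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[1]), qlogis(mean(y)), tolerance = 0.2)

  # random instances against the grid oracle and the standard fitter
  for (i in 1:5) {
    x <- rnorm(100)
    y <- rbinom(100, 1, plogis(-0.5 + 1.2 * x))
    fit <- fit_logistic_irls(y, x)
    or <- oracle_logistic_grid(y, x)
    expect_equal(unname(fit$coefficients), unname(or), tolerance = 1e-4)
    ref <- suppressWarnings(glm(y ~ x, family = binomial))
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  }
})

test_that("logistic IRLS converges with small gradient and increasing likelihood", {
  set.seed(12)
  x <- rnorm(150)
  y <- rbinom(150, 1, plogis(0.3 - 0.8 * x))
  fit <- fit_logistic_irls(y, x)
  expect_true(fit$converged)
  # final score equations: X'(y - p) ~ 0
  X <- cbind(1, x)
  p <- plogis(as.vector(X %*% fit$coefficients))
  expect_lt(sqrt(sum(crossprod(X, y - p)^2)), 1e-6)
})

test_that("logistic error contracts: separation, one class, constant predictor", {
  expect_error(fit_logistic_irls(c(0, 0, 1, 1), c(-1, -1, 1, 1)), "separation")
  expect_error(fit_logistic_irls(c(1, 1, 1, 1), c(1, 2, 3, 4)), "one class")
  expect_error(fit_logistic_irls(c(0, 1, 0, 1), c(2, 2, 2, 2)), "constant")
})

test_that("logistic fits obey logit symmetry and affine equivariance", {
  set.seed(5)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(0.4 + x))
  f1 <- fit_logistic_irls(y, x)
  f2 <- fit_logistic_irls(1 - y, x)
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients),
               tolerance = 1e-6)
  f3 <- fit_logistic_irls(y, x * 0.01)
  expect_equal(unname(f3$coefficients[2]), unname(f1$coefficients[2]) * 100,
               tolerance = 1e-4)
  p1 <- plogis(f1$coefficients[1] + f1$coefficients[2] * x)
  p3 <- plogis(f3$coefficients[1] + f3$coefficients[2] * x * 0.01)
  expect_equal(unname(p1), unname(p3), tolerance = 1e-6)
})

test_that("the interaction analysis excludes indeterminate units and needs both classes", {
  uc <- data.frame(window = rep(1:3, each = 4), iteration = rep(1:4, 3),
                   label = "w", R = 0,
                   class = c(rep("positive", 4), rep("negative", 4),
                             rep("indeterminate", 4)))
  set.seed(9)
  ab <- data.frame(window = rep(1:3, each = 4), iteration = rep(1:4, 3),
                   cushion_pct = c(50, 60, 20, 70, 10, 30, 25, 15, 40, 40, 40, 40),
                   tree_pct = c(5, 10, 30, 8, 60, 20, 35, 55, 30, 30, 30, 30))
  fits <- interaction_analysis(uc, ab)
  expect_equal(nrow(fits$data), 8)   # indeterminate window dropped
  expect_gt(fits$cushion$coefficients[2], 0)
  expect_lt(fits$tree$coefficients[2], 0)

  uc$class <- "positive"
  expect_error(interaction_analysis(uc, ab), "both positive and negative")
})
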