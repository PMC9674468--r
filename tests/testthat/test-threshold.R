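# trapezoid integral of a density curve over its grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("pooling concatenates records, preserves provenance, rejects zeros", {
  s1 <- scene(c("a", "b", "c", "d"), c(0, 1, 2, 3), c(0, 1, 0, 1),
              scene_id = "s1")
  s2 <- scene(c("a", "b", "c", "d", "e"), c(0, 5, 10, 15, 20),
              c(0, 0, 0, 0, 0), scene_id = "s2")
  nn <- list(directional_nn_distances(s1), directional_nn_distances(s2))
  pooled <- pool_distances(nn)
  expect_equal(length(pooled$distances), 7L)
  expect_equal(sort(unique(pooled$provenance$scene_id)), c("s1", "s2"))
  bad <- nn[[1]]
  bad$distance_m[2] <- 0
  expect_error(pool_distances(bad), "coincident")
})

test_that("stratified pooling conserves the sample and labels by source state", {
  sc <- random_scene(20, seed = 9, states = c("rest", "forage"))
  nn <- directional_nn_distances(sc)
  pooled <- pool_distances(nn, stratify_by_state = TRUE)
  expect_equal(length(pooled$strata), length(pooled$distances))
  expect_equal(sum(table(pooled$strata)), length(pooled$distances))
  # one-state data: the single stratum is the pooled sample
  sc1 <- random_scene(20, seed = 10, states = "travel")
  p1 <- pool_distances(directional_nn_distances(sc1), stratify_by_state = TRUE)
  expect_true(all(p1$strata == "travel"))
})

test_that("density curves integrate to ~1 on their grid", {
  set.seed(11)
  for (k in 1:5) {
    x <- rlnorm(500, meanlog = runif(1, 0, 3), sdlog = runif(1, 0.2, 1))
    for (lg in c(TRUE, FALSE)) {
      cu <- estimate_density(distance_sample(x), log_scale = lg)
      expect_true(all(cu$values >= 0))
      expect_lt(abs(trapz(cu$grid, cu$values) - 1), 0.01)
    }
  }
})

test_that("the linear-scale mode of a lognormal sample is near exp(mu - sigma^2)", {
  set.seed(12)
  x <- rlnorm(10000, meanlog = 2, sdlog = 0.25)
  cu <- estimate_density(distance_sample(x), log_scale = FALSE)
  est <- find_cutoffs(cu)
  expect_length(est$cutoffs, 0L)       # unimodal: no natural cutoff
  expect_length(est$modes, 1L)
  expect_lt(abs(est$modes - exp(2 - 0.25^2)) / exp(2 - 0.25^2), 0.05)
})

test_that("a near-degenerate sample peaks within one grid step of its value", {
  set.seed(13)
  x <- exp(rnorm(200, log(7), 1e-4))
  cu <- estimate_density(distance_sample(x))
  step <- diff(cu$grid[1:2])
  expect_lt(abs(cu$grid[which.max(cu$values)] - log(7)), step + 1e-4)
})

test_that("small samples are flagged unreliable", {
  set.seed(14)
  expect_warning(cu <- estimate_density(distance_sample(rlnorm(10))),
                 "unreliable")
  expect_true(cu$unreliable)
  expect_error(estimate_density(distance_sample(numeric(0))), "empty")
})

test_that("a unimodal sample yields no cutoff; a clear mixture yields one", {
  set.seed(15)
  uni <- rlnorm(5000, 1, 0.5)
  expect_length(estimate_thresholds(distance_sample(uni))$cutoffs, 0L)
  # two-component mixture: the detected cutoff approximates the analytic
  # antimode of the mixture pdf (dense-scan oracle, computed here)
  mix_pdf <- function(x) 0.5 * dlnorm(x, 0, 0.35) + 0.5 * dlnorm(x, 3.2, 0.35)
  xs <- seq(exp(0.5), exp(2.8), length.out = 100000)
  oracle <- xs[which.min(mix_pdf(xs))]
  x <- c(rlnorm(2500, 0, 0.35), rlnorm(2500, 3.2, 0.35))
  est <- estimate_thresholds(distance_sample(x))
  expect_length(est$cutoffs, 1L)
  expect_lt(abs(est$cutoffs - oracle) / oracle, 0.15)
})

test_that("three well-separated components give two interleaved cutoffs", {
  mix3 <- function(x) (dlnorm(x, 0, 0.3) + dlnorm(x, 3, 0.3) +
                         dlnorm(x, 6, 0.3)) / 3
  # dense-scan oracle antimodes of the analytic 3-mixture
  xs <- exp(seq(0.2, 5.8, length.out = 200000))
  f <- mix3(xs)
  lows <- c(xs[xs < exp(3)][which.min(f[xs < exp(3)])],
            xs[xs > exp(3) & xs < exp(5.5)][
              which.min(f[xs > exp(3) & xs < exp(5.5)])])
  set.seed(16)
  x <- c(rlnorm(2000, 0, 0.3), rlnorm(2000, 3, 0.3), rlnorm(2000, 6, 0.3))
  est <- estimate_thresholds(distance_sample(x))
  expect_length(est$cutoffs, 2L)
  expect_true(all(diff(est$cutoffs) > 0))
  expect_lt(abs(est$cutoffs[1] - lows[1]) / lows[1], 0.15)
  expect_lt(abs(est$cutoffs[2] - lows[2]) / lows[2], 0.15)
  # cutoffs interleave modes: mode < cutoff < next mode
  expect_length(est$modes, 3L)
  expect_true(all(est$modes[1:2] < est$cutoffs & est$cutoffs < est$modes[2:3]))
})

test_that("cutoff count is non-increasing in the prominence floor", {
  set.seed(17)
  x <- c(rlnorm(1500, 0, 0.4), rlnorm(1500, 2.5, 0.4), rlnorm(1500, 5, 0.4))
  cu <- estimate_density(distance_sample(x))
  counts <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6, 0.9),
                   function(p) length(find_cutoffs(cu, min_prominence = p)$cutoffs),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  # max_levels truncates to the deepest cutoffs, reported ascending
  est1 <- find_cutoffs(cu, max_levels = 1)
  expect_length(est1$cutoffs, 1L)
})

test_that("cutoffs scale with the data (scale equivariance)", {
  set.seed(18)
  x <- c(rlnorm(2000, 0, 0.35), rlnorm(2000, 3.2, 0.35))
  base <- estimate_thresholds(distance_sample(x))$cutoffs
  for (c_mult in c(0.037, 12, 950)) {
    scaled <- estimate_thresholds(distance_sample(x * c_mult))$cutoffs
    expect_equal(length(scaled), length(base))
    expect_lt(max(abs(scaled / base - c_mult)) / c_mult, 0.02)
  }
})

test_that("stratified estimation reports pooled and per-state thresholds", {
  set.seed(19)
  x <- c(rlnorm(400, 0, 0.35), rlnorm(400, 3.2, 0.35))
  one <- distance_sample(x, strata = rep("travel", 800))
  st <- stratified_thresholds(one)
  expect_equal(st$per_stratum$travel$cutoffs, st$cutoffs, tolerance = 1e-12)
  # a stratum below the minimum size is skipped with a warning
  mixed <- distance_sample(c(x, rlnorm(10, 1, 0.3)),
                           strata = c(rep("travel", 800), rep("rare", 10)))
  expect_warning(st2 <- stratified_thresholds(mixed), "rare")
  expect_null(st2$per_stratum$rare)
  tiny <- distance_sample(rlnorm(10, 1, 0.3), strata = rep("rare", 10))
  expect_error(suppressWarnings(stratified_thresholds(tiny)), "minimum sample")
  expect_error(stratified_thresholds(distance_sample(x)), "no strata")
})

test_that("strata from the same distribution give similar cutoffs", {
  close_enough <- vapply(1:20, function(s) {
    set.seed(20000 + s)
    draw <- function() c(rlnorm(600, 0, 0.35), rlnorm(600, 3.2, 0.35))
    sam <- distance_sample(c(draw(), draw()),
                           strata = rep(c("A", "B"), each = 1200))
    st <- stratified_thresholds(sam)
    a <- primary_cutoff(st$per_stratum$A)
    b <- primary_cutoff(st$per_stratum$B)
    abs(a - b) / min(a, b) < 0.20
  }, logical(1))
  expect_true(all(close_enough))
})

test_that("bootstrap intervals are deterministic and tighten as spread shrinks", {
  set.seed(21)
  x <- c(rlnorm(400, 0, 0.3), rlnorm(400, 3.2, 0.3))
  b1 <- bootstrap_cutoff_interval(distance_sample(x), B = 100, seed = 5)
  b2 <- bootstrap_cutoff_interval(distance_sample(x), B = 100, seed = 5)
  expect_identical(b1$intervals, b2$intervals)
  expect_equal(nrow(b1$intervals), 1L)
  # >= 90% of replicates find exactly one cutoff on this clear mixture
  expect_gte(b1$cutoff_counts[["1"]] / b1$B, 0.9)
  # near-point-mass bimodal sample: the interval collapses
  xt <- c(exp(rnorm(400, 0, 0.02)), exp(rnorm(400, 3.2, 0.02)))
  bt <- bootstrap_cutoff_interval(distance_sample(xt), B = 100, seed = 5)
  w_tight <- bt$intervals$upper - bt$intervals$lower
  w_wide <- b1$intervals$upper - b1$intervals$lower
  expect_lt(w_tight, w_wide)
  expect_error(bootstrap_cutoff_interval(distance_sample(x), B = 50, seed = 1),
               "at least 100")
})
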