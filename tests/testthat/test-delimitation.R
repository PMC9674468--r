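# the two cohesion scenarios: five tight (resting) or spread (foraging)
# individuals plus a sixth 20 m from the nearest
rest_scene <- scene(sprintf("i%02d", 1:6), x = c(0, 1, 2, 3, 4, 24),
                    y = rep(0, 6), scene_id = "rest")
forage_scene <- scene(sprintf("i%02d", 1:6), x = c(0, 25, 50, 75, 100, 120),
                      y = rep(0, 6), scene_id = "forage")

test_that("a 10 m chain separates the outlier from a tight resting cluster", {
  p <- chain_rule_partition(rest_scene, 10)
  s <- classify_units(p)
  expect_equal(s$n_groups, 1L)
  expect_equal(s$group_sizes, 5L)
  expect_equal(s$n_singletons, 1L)
  # and the singleton is the distant individual
  a <- p$assignment
  expect_equal(a$unit[a$individual_id == "i06"], "singleton")
})

test_that("a 50 m chain keeps a dispersed foraging scene together", {
  s <- classify_units(chain_rule_partition(forage_scene, 50))
  expect_equal(s$n_groups, 1L)
  expect_equal(s$group_sizes, 6L)
  # but a 10 m chain shatters it into singletons
  s10 <- classify_units(chain_rule_partition(forage_scene, 10))
  expect_equal(s10$n_singletons, 6L)
  # and 50 m wrongly absorbs the resting outlier
  s50r <- classify_units(chain_rule_partition(rest_scene, 50))
  expect_equal(s50r$group_sizes, 6L)
})

test_that("chain rule edge cases: zero threshold, empty scene, bad input", {
  sc <- random_scene(7, seed = 1)
  expect_equal(classify_units(chain_rule_partition(sc, 0))$n_singletons, 7L)
  empty <- scene(character(), numeric(), numeric())
  expect_equal(nrow(chain_rule_partition(empty, 10)$assignment), 0L)
  expect_error(chain_rule_partition(sc, -1), "nonnegative")
})

test_that("chain partitions equal the transitive-closure oracle on random scenes", {
  for (s in 1:60) {
    n <- sample(2:20, 1)
    sc <- random_scene(n, seed = 1000 + s)
    thr <- stats::runif(1, 2, 40)
    expect_identical(partition_labels(chain_rule_partition(sc, thr)),
                     bf_chain(sc, thr)[order(sc$records$individual_id)])
  }
})

test_that("chain partitions refine as the threshold decreases", {
  for (s in 1:8) {
    sc <- random_scene(15, seed = 2000 + s)
    thresholds <- sort(stats::runif(12, 0, 60))
    parts <- lapply(thresholds, function(t) chain_rule_partition(sc, t))
    ncomp <- vapply(parts, function(p) classify_units(p)$n_units, integer(1))
    expect_true(all(diff(ncomp) <= 0))
    for (k in seq_len(length(parts) - 1))
      expect_true(is_refinement(parts[[k]], parts[[k + 1]]))
  }
})

test_that("extreme thresholds give one component or all singletons", {
  for (s in 1:5) {
    sc <- random_scene(10, seed = 2100 + s)
    d <- pairwise_distances(sc)
    diam <- max(d)
    minpair <- min(d[upper.tri(d)])
    expect_equal(classify_units(chain_rule_partition(sc, diam))$n_units, 1L)
    expect_equal(
      classify_units(chain_rule_partition(sc, minpair * 0.999))$n_singletons,
      10L)
  }
})

test_that("chain partition is invariant to ordering and rigid motions", {
  sc <- random_scene(12, seed = 42)
  ref <- partition_labels(chain_rule_partition(sc, 20))
  r <- sc$records
  perm <- sample(nrow(r))
  reordered <- scene(r$individual_id[perm], r$x[perm], r$y[perm])
  expect_identical(partition_labels(chain_rule_partition(reordered, 20)), ref)
  shifted <- scene(r$individual_id, r$x + 1234.5, r$y - 987)
  expect_identical(partition_labels(chain_rule_partition(shifted, 20)), ref)
  th <- 1.1
  rotated <- scene(r$individual_id, r$x * cos(th) - r$y * sin(th),
                   r$x * sin(th) + r$y * cos(th))
  expect_identical(partition_labels(chain_rule_partition(rotated, 20)), ref)
  reflected <- scene(r$individual_id, -r$x, r$y)
  expect_identical(partition_labels(chain_rule_partition(reflected, 20)), ref)
})

test_that("focal rule matches a plain distance filter and never chains", {
  sc <- random_scene(10, seed = 77)
  expect_equal(focal_rule_group(sc, "r01", 0), "r01")
  r <- sc$records
  d <- sqrt((r$x - r$x[1])^2 + (r$y - r$y[1])^2)
  expect_equal(focal_rule_group(sc, "r01", 20),
               sort(r$individual_id[d <= 20]))
  expect_equal(focal_rule_group(sc, "r01", 1e6), sort(r$individual_id))
  expect_error(focal_rule_group(sc, "nope", 10), "not in scene")
  # focal members are always inside the focal's chain component at the same d
  for (s in 1:10) {
    sc2 <- random_scene(12, seed = 600 + s)
    mem <- focal_rule_group(sc2, "r03", 15)
    comp <- partition_labels(chain_rule_partition(sc2, 15))
    expect_true(all(comp[mem] == comp["r03"]))
  }
})

test_that("fixed-point rule matches a distance filter from the point", {
  sc <- random_scene(10, seed = 78)
  expect_equal(fixed_point_rule_group(sc, c(-500, -500), 0), character(0))
  r <- sc$records
  d <- sqrt((r$x - 50)^2 + (r$y - 50)^2)
  expect_equal(fixed_point_rule_group(sc, c(50, 50), 100),
               sort(r$individual_id[d <= 100]))
})

test_that("adaptive chain reduces to the plain chain for a single state", {
  for (s in 1:5) {
    sc <- random_scene(10, seed = 700 + s, states = "rest")
    expect_identical(
      partition_labels(adaptive_chain_partition(sc, c(rest = 12))),
      partition_labels(chain_rule_partition(sc, 12)))
  }
})

test_that("adaptive chain resolves the paired cohesion scenarios", {
  thr <- c(rest = 10, forage = 50)
  rest_b <- scene(sprintf("i%02d", 1:6), x = c(0, 1, 2, 3, 4, 24),
                  y = rep(0, 6), state = "rest")
  forage_b <- scene(sprintf("i%02d", 1:6), x = c(0, 25, 50, 75, 100, 120),
                    y = rep(0, 6), state = "forage")
  expect_equal(classify_units(adaptive_chain_partition(rest_b, thr))$n_singletons, 1L)
  expect_equal(classify_units(adaptive_chain_partition(forage_b, thr))$n_units, 1L)
})

test_that("adaptive chain uses the max threshold on mixed-state edges", {
  for (s in 1:40) {
    n <- sample(3:20, 1)
    sc <- random_scene(n, seed = 3000 + s, states = c("rest", "forage", "travel"))
    thr <- c(rest = 6, forage = 30, travel = 15)
    expect_identical(
      partition_labels(adaptive_chain_partition(sc, thr)),
      bf_adaptive(sc, thr)[order(sc$records$individual_id)])
  }
  # two-point check of the max rule: 7 m apart, rest(5) x forage(10) joins
  sc2 <- scene(c("a", "b"), c(0, 7), c(0, 0), state = c("rest", "forage"))
  expect_equal(classify_units(
    adaptive_chain_partition(sc2, c(rest = 5, forage = 10)))$n_groups, 1L)
})

test_that("adaptive chain requires a threshold or default for every state", {
  sc <- scene(c("a", "b"), c(0, 1), c(0, 0), state = c("rest", "odd"))
  expect_error(adaptive_chain_partition(sc, c(rest = 10)), "odd")
  p <- adaptive_chain_partition(sc, c(rest = 10), default_threshold = 5)
  expect_equal(classify_units(p)$n_groups, 1L)
})

test_that("unit taxonomy: singleton below 2, group at 2 or more", {
  p <- chain_rule_partition(scene(c("a", "b", "c"), c(0, 1, 50), c(0, 0, 0)), 5)
  s <- classify_units(p)
  expect_equal(s$n_groups, 1L)
  expect_equal(s$group_sizes, 2L)
  expect_equal(s$n_singletons, 1L)
  expect_equal(s$n_units, 2L)
  lone <- classify_units(chain_rule_partition(scene("a", 0, 0), 10))
  expect_equal(lone$n_groups, 0L)
  expect_equal(lone$n_singletons, 1L)
  none <- classify_units(chain_rule_partition(
    scene(character(), numeric(), numeric()), 10))
  expect_equal(none$n_units, 0L)
  expect_equal(none$n_individuals, 0L)
})
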