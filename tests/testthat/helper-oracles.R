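# Brute-force oracles, independent of the package's implementation paths.

# all-pairs Euclidean distances by explicit double loop
bf_pairwise <- function(x, y) {
  n <- length(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  d
}

# directional NN by explicit scan: strictly greater along-bearing coordinate
# (ties: perpendicular coordinate, then id), minimum Euclidean distance
bf_directional_nn <- function(sc, bearing = 0) {
  r <- sc$records
  th <- bearing * pi / 180
  u <- r$x * sin(th) + r$y * cos(th)
  v <- r$x * cos(th) - r$y * sin(th)
  out <- NULL
  for (i in seq_len(nrow(r))) {
    best <- Inf; best_j <- NA
    for (j in seq_len(nrow(r))) {
      if (j == i) next
      ahead <- (u[j] > u[i]) || (u[j] == u[i] && v[j] > v[i]) ||
        (u[j] == u[i] && v[j] == v[i] &&
           r$individual_id[j] > r$individual_id[i])
      if (!ahead) next
      d <- sqrt((r$x[j] - r$x[i])^2 + (r$y[j] - r$y[i])^2)
      if (d < best || (d == best && r$individual_id[j] <
                       r$individual_id[best_j])) {
        best <- d; best_j <- j
      }
    }
    if (is.finite(best))
      out <- rbind(out, data.frame(source_id = r$individual_id[i],
                                   neighbor_id = r$individual_id[best_j],
                                   distance_m = best,
                                   stringsAsFactors = FALSE))
  }
  out
}

# transitive closure of an adjacency relation by Floyd-Warshall reachability;
# returns canonical component labels (by minimum member id)
bf_components <- function(ids, adj) {
  n <- length(ids)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n))
    reach <- reach | (reach[, k] %o% reach[k, ])
  comp <- vapply(seq_len(n), function(i) min(ids[reach[i, ]]), ids[1])
  stats::setNames(comp, ids)
}

bf_chain <- function(sc, threshold) {
  r <- sc$records
  d <- bf_pairwise(r$x, r$y)
  bf_components(r$individual_id, d <= threshold)
}

bf_adaptive <- function(sc, thresholds, default = NULL) {
  r <- sc$records
  t_i <- unname(thresholds[r$state])
  if (!is.null(default)) t_i[is.na(t_i)] <- default
  d <- bf_pairwise(r$x, r$y)
  n <- nrow(r)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- d[i, j] <= max(t_i[i], t_i[j])
  bf_components(r$individual_id, adj)
}

# component labels of a group_partition keyed by individual, canonicalized to
# the minimum member id so they compare with bf_components output
partition_labels <- function(p) {
  a <- p$assignment
  min_id <- vapply(split(a$individual_id, a$component), min, character(1))
  stats::setNames(unname(min_id[as.character(a$component)]), a$individual_id)
}

# adjusted Rand by explicit enumeration of the pair-confusion counts
bf_ari <- function(la, lb) {
  stopifnot(identical(names(la), names(lb)))
  n <- length(la)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- la[i] == la[j]; sb <- lb[i] == lb[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(if (n10 + n01 == 0) 1 else 0)
  2 * (n11 * n00 - n10 * n01) / denom
}

# random scene generator for property tests
random_scene <- function(n, seed, side = 100, states = NULL,
                         scene_id = paste0("rs", seed)) {
  set.seed(seed)
  st <- if (is.null(states)) NULL else sample(states, n, replace = TRUE)
  scene(sprintf("r%02d", seq_len(n)),
        x = stats::runif(n, 0, side), y = stats::runif(n, 0, side),
        scene_id = scene_id, state = st)
}

# TRUE iff partition `fine` refines partition `coarse` (same individuals)
is_refinement <- function(fine, coarse) {
  lf <- partition_labels(fine); lc <- partition_labels(coarse)
  lc <- lc[names(lf)]
  all(vapply(split(lc, lf), function(v) length(unique(v)) == 1L, logical(1)))
}
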