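#' Pool directional nearest-neighbor distances across scenes
#'
#' Concatenates directional NN records (see [directional_nn_distances()]) from
#' one or many scenes into a single distance sample, optionally stratified by
#' the source individual's behavioral state. Threshold estimation operates on
#' these pooled samples: one snapshot rarely carries enough distances to
#' resolve the within-group and between-group scales.
#'
#' @param nn_records a data frame of directional NN records, or a list of such
#'   data frames (one per scene).
#' @param stratify_by_state if `TRUE`, label each distance with the source
#'   individual's behavioral state for per-state threshold estimation.
#' @return An object of class `"distance_sample"`: a list with `distances`
#'   (metres), `strata` (state labels or `NULL`) and `provenance` (data frame
#'   of `scene_id`, `source_id`, `neighbor_id`).
#' @export
pool_distances <- function(nn_records, stratify_by_state = FALSE) {
  if (is.data.frame(nn_records)) nn_records <- list(nn_records)
  nn <- do.call(rbind, nn_records)
  if (is.null(nn) || nrow(nn) == 0)
    stop("no directional NN records to pool", call. = FALSE)
  bad <- !is.finite(nn$distance_m) | nn$distance_m <= 0
  if (any(bad)) {
    k <- which(bad)[1]
    stop("nonpositive directional NN distance for pair ", nn$source_id[k], "-",
         nn$neighbor_id[k], " in scene ", nn$scene_id[k],
         "; coincident positions are a data problem", call. = FALSE)
  }
  strata <- NULL
  if (stratify_by_state) {
    strata <- nn$source_state
    if (is.null(strata)) strata <- rep(NA_character_, nrow(nn))
  }
  structure(
    list(distances = nn$distance_m, strata = strata,
         provenance = nn[, c("scene_id", "source_id", "neighbor_id")]),
    class = "distance_sample")
}

#' Construct a distance sample directly from distances
#'
#' @param distances positive distances in metres.
#' @param strata optional parallel vector of stratum (state) labels.
#' @param provenance optional data frame of per-distance provenance.
#' @return A `"distance_sample"` (see [pool_distances()]).
#' @export
distance_sample <- function(distances, strata = NULL, provenance = NULL) {
  distances <- as.numeric(distances)
  if (any(!is.finite(distances) | distances <= 0))
    stop("all distances must be finite and > 0", call. = FALSE)
  if (!is.null(strata) && length(strata) != length(distances))
    stop("`strata` must parallel `distances`", call. = FALSE)
  structure(list(distances = distances,
                 strata = if (is.null(strata)) NULL else as.character(strata),
                 provenance = provenance),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat("<distance_sample> n = ", length(x$distances), ", range ",
      signif(min(x$distances), 4), "-", signif(max(x$distances), 4), " m",
      sep = "")
  if (!is.null(x$strata))
    cat("; strata:", paste(names(table(x$strata)), collapse = ", "))
  cat("\n")
  invisible(x)
}

# minimum sample size below which density-based threshold estimates are
# flagged unreliable
.MIN_N <- 30

#' Kernel density estimate of a distance sample
#'
#' Gaussian-kernel density of the pooled directional NN distances, by default
#' on the logarithmic scale: distances are positive and strongly right-skewed,
#' and the valley between a metres-scale within-group mode and a
#' hundreds-of-metres between-group mode is invisible on a linear grid.
#' Cutoffs found on the log scale are back-transformed to metres by
#' [find_cutoffs()].
#'
#' @param sample a `"distance_sample"` or a bare numeric vector of distances.
#' @param bw bandwidth rule: `"nrd0"` (Silverman, the default), `"SJ"`
#'   (Sheather-Jones), or a single numeric bandwidth on the analysis scale.
#' @param log_scale analyze `log(distance)` (default `TRUE`).
#' @param n_grid number of evaluation points (default 512).
#' @return An object of class `"density_curve"`: list with `grid` (analysis
#'   scale: log-metres when `log_scale`), `values` (density, integrating to ~1
#'   over the grid), `bandwidth`, `log_scale`, `n` and `unreliable` (flagged
#'   when `n < 30`).
#' @export
estimate_density <- function(sample, bw = "nrd0", log_scale = TRUE,
                             n_grid = 512) {
  x <- if (inherits(sample, "distance_sample")) sample$distances else
    distance_sample(sample)$distances
  n <- length(x)
  if (n == 0) stop("empty distance sample", call. = FALSE)
  unreliable <- n < .MIN_N
  if (unreliable)
    warning("only ", n, " distances (< ", .MIN_N,
            "); density and cutoffs flagged unreliable", call. = FALSE)
  y <- if (log_scale) log(x) else x
  h <- if (is.numeric(bw)) bw
  else switch(match.arg(bw, c("nrd0", "SJ")),
              nrd0 = stats::bw.nrd0(y), SJ = stats::bw.SJ(y))
  if (!is.finite(h) || h <= 0) {
    # degenerate spread (e.g. all-equal sample): fall back to a tiny width
    h <- max(1e-8, abs(mean(y)) * 1e-6)
  }
  from <- min(y) - 3 * h
  if (!log_scale) from <- max(0, from)
  de <- stats::density(y, bw = h, kernel = "gaussian", n = n_grid,
                       from = from, to = max(y) + 3 * h)
  # renormalize over the evaluation grid: the linear-scale grid is clipped at
  # zero and can otherwise lose kernel mass for samples piled near the origin
  mass <- sum(diff(de$x) * (de$y[-1] + de$y[-length(de$y)]) / 2)
  de$y <- de$y / mass
  structure(list(grid = de$x, values = de$y, bandwidth = h,
                 log_scale = log_scale, n = n, unreliable = unreliable),
            class = "density_curve")
}

# interior local extrema of a numeric series: indices where the first
# difference changes sign; flat stretches inherit the preceding slope
.local_extrema <- function(v) {
  s <- sign(diff(v))
  for (k in seq_along(s)[-1]) if (s[k] == 0) s[k] <- s[k - 1]
  list(maxima = which(s[-length(s)] > 0 & s[-1] < 0) + 1L,
       minima = which(s[-length(s)] < 0 & s[-1] > 0) + 1L)
}

#' Locate cutoff distances (antimodes) from the gradient of a density curve
#'
#' Cutoff points separate the within-group scale from coarser scales of
#' spatial organization. They are identified as interior local minima
#' (antimodes) of the density curve — grid points where the numerical gradient
#' changes sign from negative to positive — lying between modes. Shallow
#' valleys are discarded: an antimode is retained only when its relative
#' prominence, `(min(flanking mode heights) - antimode height) /
#' min(flanking mode heights)`, reaches `min_prominence`; discarding a valley
#' merges its flanking modes. A unimodal curve yields an empty cutoff list,
#' reported explicitly as "no natural cutoff".
#'
#' @param curve a `"density_curve"` from [estimate_density()].
#' @param min_prominence minimum relative prominence in `[0, 1)` (default 0.10).
#' @param min_depth minimum absolute valley depth — the drop from the lower
#'   flanking mode to the antimode as a fraction of the global density maximum
#'   (default 0.01). This is the noise floor: a lone outlier in the sample
#'   raises a minuscule kernel bump in the tail whose valley has *relative*
#'   prominence near 1 (its flanking bump is tiny) yet descends through almost
#'   no density; such valleys are not organizational structure.
#' @param max_levels retain at most this many cutoffs, deepest (most
#'   prominent) first (default `Inf`).
#' @return An object of class `"threshold_estimate"`: list with `cutoffs`
#'   (ascending, metres), `modes` (ascending, metres), `prominence` (parallel
#'   to `cutoffs`), `n`, `bandwidth`, `log_scale`, `unreliable`, and
#'   `per_stratum` (`NULL` here; see [stratified_thresholds()]). Ascending
#'   cutoffs correspond to nested organizational levels: with two or more
#'   cutoffs the units they delimit can be termed subgroup, group, supergroup.
#' @export
find_cutoffs <- function(curve, min_prominence = 0.10, min_depth = 0.01,
                         max_levels = Inf) {
  stopifnot(inherits(curve, "density_curve"))
  if (min_prominence < 0 || min_prominence >= 1)
    stop("`min_prominence` must be in [0, 1)", call. = FALSE)
  if (min_depth < 0 || min_depth >= 1)
    stop("`min_depth` must be in [0, 1)", call. = FALSE)
  v <- curve$values
  vmax <- max(v)
  ex <- .local_extrema(v)
  maxima <- sort(ex$maxima)
  minima <- sort(ex$minima)
  # keep only antimodes strictly between two maxima; iteratively drop the
  # weakest antimode failing the prominence or depth floor and merge its
  # flanking modes (the lower flank disappears into the survivor)
  repeat {
    minima <- minima[vapply(minima, function(m)
      any(maxima < m) && any(maxima > m), logical(1))]
    if (!length(minima)) break
    flanks <- vapply(minima, function(m) {
      lo <- max(maxima[maxima < m]); hi <- min(maxima[maxima > m])
      min(v[lo], v[hi])
    }, numeric(1))
    prom <- ifelse(flanks > 0, (flanks - v[minima]) / flanks, 0)
    depth <- (flanks - v[minima]) / vmax
    fail <- prom < min_prominence | depth < min_depth
    if (!any(fail)) break
    # drop the shallowest failing valley first (noise before structure)
    k <- which(fail)[which.min(depth[fail])]
    m <- minima[k]
    lo <- max(maxima[maxima < m]); hi <- min(maxima[maxima > m])
    drop_mode <- if (v[lo] <= v[hi]) lo else hi
    maxima <- setdiff(maxima, drop_mode)
    minima <- minima[-k]
  }
  if (length(minima)) {
    prom <- vapply(minima, function(m) {
      lo <- max(maxima[maxima < m]); hi <- min(maxima[maxima > m])
      flank <- min(v[lo], v[hi])
      (flank - v[m]) / flank
    }, numeric(1))
    # absolute valley depth, scaled by the global density maximum: unlike the
    # relative prominence it is not inflated by a minuscule flanking mode, so
    # it is the right statistic for *choosing among* retained cutoffs
    depth <- vapply(minima, function(m) {
      lo <- max(maxima[maxima < m]); hi <- min(maxima[maxima > m])
      (min(v[lo], v[hi]) - v[m]) / max(v)
    }, numeric(1))
    if (is.finite(max_levels) && length(minima) > max_levels) {
      keep <- order(prom, decreasing = TRUE)[seq_len(max_levels)]
      minima <- minima[keep]; prom <- prom[keep]; depth <- depth[keep]
      ord <- order(minima)
      minima <- minima[ord]; prom <- prom[ord]; depth <- depth[ord]
    }
  } else prom <- depth <- numeric(0)
  back <- if (curve$log_scale) exp else identity
  structure(
    list(cutoffs = back(curve$grid[minima]),
         modes = back(curve$grid[sort(maxima)]),
         prominence = prom, depth = depth,
         n = curve$n, bandwidth = curve$bandwidth,
         log_scale = curve$log_scale, unreliable = curve$unreliable,
         per_stratum = NULL),
    class = "threshold_estimate")
}

#' The primary cutoff of a threshold estimate
#'
#' When an estimate carries several cutoffs (multiple organizational levels,
#' or residual sampling noise), downstream steps that need a single group
#' threshold use the cutoff with the greatest absolute valley depth — the drop
#' from the lower flanking mode to the antimode, scaled by the global density
#' maximum. Depth, unlike the relative prominence used for retention, is not
#' inflated when a valley happens to sit next to a minuscule noise mode.
#'
#' @param estimate a `"threshold_estimate"`.
#' @return A single cutoff in metres, or `NA_real_` when no cutoff was found.
#' @export
primary_cutoff <- function(estimate) {
  stopifnot(inherits(estimate, "threshold_estimate"))
  if (!length(estimate$cutoffs)) return(NA_real_)
  estimate$cutoffs[which.max(estimate$depth)]
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat("<threshold_estimate> n = ", x$n,
      if (x$unreliable) " (UNRELIABLE: small sample)", "\n", sep = "")
  if (length(x$cutoffs))
    cat("  cutoffs (m): ", paste(signif(x$cutoffs, 4), collapse = ", "),
        "  [prominence ", paste(signif(x$prominence, 3), collapse = ", "),
        "]\n", sep = "")
  else cat("  no natural cutoff detected (unimodal at this prominence)\n")
  cat("  modes (m): ", paste(signif(x$modes, 4), collapse = ", "), "\n", sep = "")
  if (!is.null(x$per_stratum))
    for (s in names(x$per_stratum))
      cat("  [", s, "] cutoffs (m): ",
          paste(signif(x$per_stratum[[s]]$cutoffs, 4), collapse = ", "),
          "\n", sep = "")
  invisible(x)
}

#' One-call threshold estimation from a distance sample
#'
#' Convenience wrapper: [estimate_density()] then [find_cutoffs()].
#'
#' @inheritParams estimate_density
#' @inheritParams find_cutoffs
#' @return A `"threshold_estimate"`.
#' @export
estimate_thresholds <- function(sample, bw = "nrd0", log_scale = TRUE,
                                n_grid = 512, min_prominence = 0.10,
                                min_depth = 0.01, max_levels = Inf) {
  find_cutoffs(estimate_density(sample, bw = bw, log_scale = log_scale,
                                n_grid = n_grid),
               min_prominence = min_prominence, min_depth = min_depth,
               max_levels = max_levels)
}

#' Behavior-stratified threshold estimation
#'
#' Runs cutoff detection independently on each behavioral stratum and on the
#' pooled sample, giving one threshold per behavioral state for use with
#' [adaptive_chain_partition()]. Strata with fewer than 30 distances are
#' skipped (with a warning) rather than estimated unreliably.
#'
#' @param sample a `"distance_sample"` carrying `strata` labels (see
#'   [pool_distances()] with `stratify_by_state = TRUE`).
#' @inheritParams estimate_thresholds
#' @return A `"threshold_estimate"` for the pooled sample whose `per_stratum`
#'   element maps each usable state to its own `"threshold_estimate"`.
#' @export
stratified_thresholds <- function(sample, bw = "nrd0", log_scale = TRUE,
                                  n_grid = 512, min_prominence = 0.10,
                                  min_depth = 0.01, max_levels = Inf) {
  stopifnot(inherits(sample, "distance_sample"))
  if (is.null(sample$strata))
    stop("`sample` carries no strata; pool with stratify_by_state = TRUE",
         call. = FALSE)
  pooled <- estimate_thresholds(sample, bw = bw, log_scale = log_scale,
                                n_grid = n_grid,
                                min_prominence = min_prominence, min_depth = min_depth,
                                max_levels = max_levels)
  states <- sort(unique(sample$strata))
  per <- list()
  for (s in states) {
    idx <- which(sample$strata == s)
    if (length(idx) < .MIN_N) {
      warning("stratum '", s, "' has only ", length(idx),
              " distances (< ", .MIN_N, "); skipped", call. = FALSE)
      next
    }
    per[[s]] <- estimate_thresholds(
      distance_sample(sample$distances[idx]),
      bw = bw, log_scale = log_scale, n_grid = n_grid,
      min_prominence = min_prominence, min_depth = min_depth,
               max_levels = max_levels)
  }
  if (!length(per))
    stop("all strata below the minimum sample size (", .MIN_N, ")",
         call. = FALSE)
  pooled$per_stratum <- per
  pooled
}

#' Bootstrap percentile intervals for cutoff distances
#'
#' Nonparametric bootstrap over the pooled distances: each replicate resamples
#' the distances with replacement and reruns density estimation and cutoff
#' detection. Replicate cutoffs are matched to the point-estimate cutoffs by
#' nearest distance; for each point cutoff the 2.5/97.5 percentile interval of
#' its matched replicate values is reported, together with the distribution of
#' the number of cutoffs per replicate (a stability diagnostic).
#'
#' @param sample a `"distance_sample"` or numeric vector of distances.
#' @param B number of bootstrap replicates, `>= 100`.
#' @param seed integer seed for the resampling (required: no hidden state).
#' @inheritParams estimate_thresholds
#' @return A list of class `"cutoff_bootstrap"`: `intervals` (data frame
#'   `cutoff`, `lower`, `upper`, `match_rate`), `cutoff_counts` (table of
#'   cutoffs-per-replicate), `B`, `seed`.
#' @export
bootstrap_cutoff_interval <- function(sample, B = 200, seed, bw = "nrd0",
                                      log_scale = TRUE, n_grid = 512,
                                      min_prominence = 0.10,
                                      min_depth = 0.01,
                                      max_levels = Inf) {
  if (B < 100) stop("`B` must be at least 100", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  x <- if (inherits(sample, "distance_sample")) sample$distances
  else as.numeric(sample)
  point <- estimate_thresholds(distance_sample(x), bw = bw,
                               log_scale = log_scale, n_grid = n_grid,
                               min_prominence = min_prominence,
                               max_levels = max_levels)
  k <- length(point$cutoffs)
  set.seed(as.integer(seed))
  matched <- matrix(NA_real_, nrow = B, ncol = max(k, 1))
  counts <- integer(B)
  for (b in seq_len(B)) {
    xb <- sample(x, replace = TRUE)
    est <- suppressWarnings(
      estimate_thresholds(distance_sample(xb), bw = bw,
                          log_scale = log_scale, n_grid = n_grid,
                          min_prominence = min_prominence, min_depth = min_depth,
                          max_levels = max_levels))
    counts[b] <- length(est$cutoffs)
    if (k > 0 && length(est$cutoffs) > 0) {
      for (j in seq_len(k)) {
        d <- abs(log(est$cutoffs) - log(point$cutoffs[j]))
        matched[b, j] <- est$cutoffs[which.min(d)]
      }
    }
  }
  intervals <- if (k > 0) {
    data.frame(
      cutoff = point$cutoffs,
      lower = vapply(seq_len(k), function(j)
        stats::quantile(matched[, j], 0.025, na.rm = TRUE, names = FALSE),
        numeric(1)),
      upper = vapply(seq_len(k), function(j)
        stats::quantile(matched[, j], 0.975, na.rm = TRUE, names = FALSE),
        numeric(1)),
      match_rate = vapply(seq_len(k), function(j)
        mean(!is.na(matched[, j])), numeric(1)))
  } else data.frame(cutoff = numeric(), lower = numeric(), upper = numeric(),
                    match_rate = numeric())
  structure(list(intervals = intervals, cutoff_counts = table(counts),
                 B = B, seed = as.integer(seed)),
            class = "cutoff_bootstrap")
}
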