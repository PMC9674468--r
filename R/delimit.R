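#' @importFrom igraph graph_from_adjacency_matrix components
NULL

# Build a group_partition from a component membership vector. Components are
# relabelled 1..k in order of their minimum member identifier so output is
# deterministic regardless of the graph traversal order.
.new_partition <- function(scene_id, ids, membership) {
  if (length(ids) == 0) {
    return(structure(
      list(scene_id = scene_id,
           assignment = data.frame(individual_id = character(),
                                   component = integer(),
                                   unit = character(),
                                   stringsAsFactors = FALSE)),
      class = "group_partition"))
  }
  min_id <- vapply(split(ids, membership), min, character(1))
  relabel <- match(names(min_id), names(sort(min_id)))
  names(relabel) <- names(min_id)
  comp <- unname(relabel[as.character(membership)])
  sizes <- table(comp)
  unit <- ifelse(sizes[as.character(comp)] >= 2, "group", "singleton")
  ord <- order(ids)
  structure(
    list(scene_id = scene_id,
         assignment = data.frame(individual_id = ids[ord],
                                 component = comp[ord],
                                 unit = unname(unit)[ord],
                                 stringsAsFactors = FALSE)),
    class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  s <- classify_units(x)
  cat("<group_partition> ", x$scene_id, ": ", s$n_individuals,
      " individuals in ", s$n_groups, " group(s) + ", s$n_singletons,
      " singleton(s)\n", sep = "")
  invisible(x)
}

# connected components of a logical adjacency matrix over the scene
.partition_from_adjacency <- function(scene_obj, adj) {
  ids <- scene_obj$records$individual_id
  if (length(ids) == 0) return(.new_partition(scene_obj$scene_id, ids, integer()))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  .new_partition(scene_obj$scene_id, ids, memb)
}

#' Chain rule: single-linkage group delimitation at a fixed threshold
#'
#' Links any individual within `threshold` metres of any current group member:
#' groups are the connected components of the graph with an edge wherever the
#' pairwise distance is at most the threshold (inclusive). This is the "10 m
#' chain rule" family of field definitions, equivalent to cutting a
#' single-linkage clustering at the threshold height.
#'
#' @param scene_obj a `scene`.
#' @param threshold linking distance in metres, `>= 0`.
#' @return A `"group_partition"`: a list with `scene_id` and an `assignment`
#'   data frame (`individual_id`, `component`, `unit`), where `unit` is
#'   `"group"` for components of two or more members and `"singleton"`
#'   otherwise. Component labels are ordered by minimum member identifier.
#' @examples
#' sc <- scene(letters[1:6], x = c(0, 1, 2, 3, 4, 24), y = rep(0, 6))
#' chain_rule_partition(sc, 10)  # the distant sixth individual is separated
#' chain_rule_partition(sc, 50)  # ...but absorbed at 50 m
#' @seealso [adaptive_chain_partition()] for behavior-dependent thresholds.
#' @export
chain_rule_partition <- function(scene_obj, threshold) {
  stopifnot(inherits(scene_obj, "scene"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0)
    stop("`threshold` must be a single nonnegative number", call. = FALSE)
  d <- pairwise_distances(scene_obj)
  .partition_from_adjacency(scene_obj, d <= threshold)
}

#' Behavior-adaptive chain rule
#'
#' A chain rule whose linking distance depends on behavioral state: the edge
#' between two individuals in the same state uses that state's threshold; an
#' edge between individuals in different states uses the larger of the two
#' states' thresholds (the grouping-conservative choice, which avoids
#' splitting a spatially contiguous mixed-behavior cluster).
#'
#' @param scene_obj a `scene` whose records carry behavioral states.
#' @param thresholds_by_state named numeric vector mapping state labels to
#'   linking distances in metres.
#' @param default_threshold threshold applied to states (or missing states)
#'   not named in `thresholds_by_state`; required if any such state occurs.
#' @return A `"group_partition"` (see [chain_rule_partition()]).
#' @examples
#' sc <- scene(letters[1:4], x = c(0, 8, 40, 60), y = rep(0, 4),
#'             state = c("rest", "rest", "forage", "forage"))
#' adaptive_chain_partition(sc, c(rest = 10, forage = 50))
#' @export
adaptive_chain_partition <- function(scene_obj, thresholds_by_state,
                                     default_threshold = NULL) {
  stopifnot(inherits(scene_obj, "scene"))
  if (is.null(names(thresholds_by_state)) || any(names(thresholds_by_state) == ""))
    stop("`thresholds_by_state` must be a named numeric vector", call. = FALSE)
  if (any(thresholds_by_state < 0) ||
      (!is.null(default_threshold) && default_threshold < 0))
    stop("thresholds must be nonnegative", call. = FALSE)
  st <- scene_obj$records$state
  t_i <- unname(thresholds_by_state[st])
  missing_state <- is.na(t_i)
  if (any(missing_state)) {
    if (is.null(default_threshold))
      stop("no threshold for state(s) ",
           paste(unique(ifelse(is.na(st[missing_state]), "<NA>",
                               st[missing_state])), collapse = ", "),
           " and no `default_threshold` given", call. = FALSE)
    t_i[missing_state] <- default_threshold
  }
  if (length(t_i) == 0)
    return(.new_partition(scene_obj$scene_id, character(), integer()))
  d <- pairwise_distances(scene_obj)
  tmat <- outer(t_i, t_i, pmax) # same state -> own threshold; mixed -> max
  .partition_from_adjacency(scene_obj, d <= tmat)
}

#' Focal-individual rule
#'
#' All individuals within `radius` metres of one designated focal individual
#' are members of the focal's group; there is no chaining beyond the focal's
#' radius (contrast with [chain_rule_partition()]).
#'
#' @param scene_obj a `scene`.
#' @param focal_id identifier of the focal individual (must be in the scene).
#' @param radius inclusion radius in metres, `>= 0`.
#' @return Sorted character vector of member identifiers, always including the
#'   focal individual.
#' @export
focal_rule_group <- function(scene_obj, focal_id, radius) {
  stopifnot(inherits(scene_obj, "scene"))
  if (radius < 0) stop("`radius` must be nonnegative", call. = FALSE)
  r <- scene_obj$records
  i <- match(as.character(focal_id), r$individual_id)
  if (is.na(i)) stop("focal individual '", focal_id, "' not in scene", call. = FALSE)
  d <- sqrt((r$x - r$x[i])^2 + (r$y - r$y[i])^2)
  sort(r$individual_id[d <= radius])
}

#' Fixed-point rule
#'
#' All individuals within `radius` metres of a fixed location (typically the
#' research vessel) form the group; the result may be empty.
#'
#' @param scene_obj a `scene`.
#' @param point `c(x, y)` in metres.
#' @param radius inclusion radius in metres, `>= 0`.
#' @return Sorted character vector of member identifiers (possibly empty).
#' @export
fixed_point_rule_group <- function(scene_obj, point, radius) {
  stopifnot(inherits(scene_obj, "scene"))
  point <- as.numeric(point)
  if (length(point) != 2 || !all(is.finite(point)))
    stop("`point` must be a finite c(x, y)", call. = FALSE)
  if (radius < 0) stop("`radius` must be nonnegative", call. = FALSE)
  r <- scene_obj$records
  d <- sqrt((r$x - point[1])^2 + (r$y - point[2])^2)
  sort(r$individual_id[d <= radius])
}

#' Classify the units of a partition: singletons, groups, and the sighting
#'
#' Labels each component of a partition a *singleton* (exactly one member) or
#' a *group* (two or more members); the whole observation — singletons and
#' groups together — is the *sighting*. A lone individual is never a group.
#' Singletons are counted separately rather than discarded so they can be
#' included in downstream analyses.
#'
#' @param partition a `"group_partition"`.
#' @return A list of class `"sighting_summary"` with `scene_id`,
#'   `n_individuals`, `n_units` (components in the sighting), `n_singletons`,
#'   `n_groups`, and `group_sizes` (sizes of groups only, decreasing).
#' @export
classify_units <- function(partition) {
  stopifnot(inherits(partition, "group_partition"))
  a <- partition$assignment
  sizes <- as.integer(table(a$component))
  structure(
    list(scene_id = partition$scene_id,
         n_individuals = nrow(a),
         n_units = length(sizes),
         n_singletons = sum(sizes == 1L),
         n_groups = sum(sizes >= 2L),
         group_sizes = sort(sizes[sizes >= 2L], decreasing = TRUE)),
    class = "sighting_summary")
}

#' @export
print.sighting_summary <- function(x, ...) {
  cat("<sighting> ", x$scene_id, ": ", x$n_groups, " group(s) ",
      if (x$n_groups) paste0("(sizes ", paste(x$group_sizes, collapse = ", "), ") "),
      "+ ", x$n_singletons, " singleton(s), ", x$n_individuals,
      " individuals\n", sep = "")
  invisible(x)
}

#' Convert a member set to a whole-scene partition
#'
#' The member set (e.g. from [focal_rule_group()] or
#' [fixed_point_rule_group()]) becomes one component; every other individual
#' in the scene becomes a singleton. This makes radius-based rules comparable
#' with chain rules via [partition_agreement()].
#'
#' @param scene_obj the `scene` the members came from.
#' @param members character vector of member identifiers.
#' @return A `"group_partition"`.
#' @export
members_to_partition <- function(scene_obj, members) {
  stopifnot(inherits(scene_obj, "scene"))
  ids <- scene_obj$records$individual_id
  if (!all(members %in% ids))
    stop("members not in scene: ",
         paste(setdiff(members, ids), collapse = ", "), call. = FALSE)
  memb <- seq_along(ids) + 1L
  memb[ids %in% members] <- 1L
  .new_partition(scene_obj$scene_id, ids, memb)
}
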