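#' Construct a scene: an instantaneous snapshot of individual positions
#'
#' A scene is the sampling-unit substrate of field group delimitation: one
#' instantaneous observation of a set of individuals, each with planar
#' coordinates in metres and, optionally, a behavioral state and a body
#' length. All delimitation rules and distance measurements in this package
#' operate on scenes.
#'
#' @param individual_id character vector of unique identifiers.
#' @param x,y numeric planar coordinates in metres (easting, northing).
#' @param scene_id a single identifier for the snapshot.
#' @param state optional character vector of behavioral state labels
#'   (e.g. `"rest"`, `"forage"`), recycled if length 1.
#' @param body_length optional numeric body lengths in metres, all positive.
#' @param window optional rectangular survey bounds
#'   `c(xmin, xmax, ymin, ymax)` in metres; when present all individuals must
#'   lie inside it.
#' @param observer optional observer position `c(x, y)` in metres.
#'
#' @return An object of class `"scene"`: a list with elements `scene_id`,
#'   `records` (a data frame with columns `individual_id`, `x`, `y`, `state`,
#'   `body_length`), `window` and `observer`.
#' @examples
#' sc <- scene(c("a", "b", "c"), x = c(0, 3, 50), y = c(0, 4, 0))
#' n_individuals(sc)
#' @export
scene <- function(individual_id, x, y, scene_id = "scene1", state = NULL,
                  body_length = NULL, window = NULL, observer = NULL) {
  individual_id <- as.character(individual_id)
  n <- length(individual_id)
  if (length(x) != n || length(y) != n)
    stop("`x` and `y` must have one value per individual", call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyDuplicated(individual_id))
    stop("duplicate individual_id within a scene: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "),
         call. = FALSE)
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("all coordinates must be finite", call. = FALSE)
  if (is.null(state)) state <- rep(NA_character_, n)
  if (length(state) == 1L && n > 1L) state <- rep(state, n)
  state <- as.character(state)
  if (length(state) != n) stop("`state` must have one value per individual", call. = FALSE)
  if (is.null(body_length)) body_length <- rep(NA_real_, n)
  body_length <- as.numeric(body_length)
  if (length(body_length) != n)
    stop("`body_length` must have one value per individual", call. = FALSE)
  if (any(!is.na(body_length) & body_length <= 0))
    stop("body_length must be > 0 where present", call. = FALSE)
  if (!is.null(window)) {
    window <- as.numeric(window)
    if (length(window) != 4 || window[1] >= window[2] || window[3] >= window[4])
      stop("`window` must be c(xmin, xmax, ymin, ymax) with positive extent",
           call. = FALSE)
    inside <- x >= window[1] & x <= window[2] & y >= window[3] & y <= window[4]
    if (n > 0 && !all(inside))
      stop("individuals outside the survey window: ",
           paste(individual_id[!inside], collapse = ", "), call. = FALSE)
  }
  if (!is.null(observer)) {
    observer <- as.numeric(observer)
    if (length(observer) != 2 || !all(is.finite(observer)))
      stop("`observer` must be a finite c(x, y)", call. = FALSE)
  }
  structure(
    list(scene_id = as.character(scene_id)[1],
         records = data.frame(individual_id = individual_id, x = x, y = y,
                              state = state, body_length = body_length,
                              stringsAsFactors = FALSE),
         window = window, observer = observer),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> ", x$scene_id, ": ", nrow(x$records), " individuals", sep = "")
  st <- unique(x$records$state)
  st <- st[!is.na(st)]
  if (length(st)) cat("; states:", paste(st, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @rdname scene
#' @param scene_obj a `scene`.
#' @export
n_individuals <- function(scene_obj) {
  stopifnot(inherits(scene_obj, "scene"))
  nrow(scene_obj$records)
}

# mean Earth radius (m), spherical model
.R_EARTH <- 6371000

#' Project longitude/latitude to local planar coordinates (metres)
#'
#' Equirectangular (local tangent-plane) projection about a reference point:
#' `x = R * cos(lat_ref) * dlon`, `y = R * dlat` with angles in radians and
#' `R = 6371 km` (spherical Earth). Distances are preserved to first order at
#' the reference; adequate for scenes spanning at most a few kilometres.
#'
#' @param lon,lat numeric vectors of coordinates in decimal degrees.
#' @param reference `c(lon, lat)` of the projection origin, decimal degrees.
#' @return A data frame with columns `x` and `y` in metres.
#' @examples
#' to_planar(0, 0.001, reference = c(0, 0)) # ~111.2 m north of the origin
#' @export
to_planar <- function(lon, lat, reference) {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  reference <- as.numeric(reference)
  if (length(reference) != 2) stop("`reference` must be c(lon, lat)", call. = FALSE)
  if (any(abs(lat) > 90) || abs(reference[2]) > 90)
    stop("latitude out of range [-90, 90]", call. = FALSE)
  dlon <- lon - reference[1]
  dlat <- lat - reference[2]
  if (any(abs(dlon) > 1 | abs(dlat) > 1))
    warning("points more than 1 degree from the reference; ",
            "the local tangent-plane assumption may not hold", call. = FALSE)
  data.frame(
    x = .R_EARTH * cos(reference[2] * pi / 180) * dlon * pi / 180,
    y = .R_EARTH * dlat * pi / 180
  )
}

#' Pairwise Euclidean distance matrix of a scene
#'
#' @param scene_obj a `scene`.
#' @return A symmetric numeric matrix (metres) with zero diagonal, rows and
#'   columns named by `individual_id`. A scene with no individuals yields a
#'   0 x 0 matrix.
#' @export
pairwise_distances <- function(scene_obj) {
  stopifnot(inherits(scene_obj, "scene"))
  r <- scene_obj$records
  if (nrow(r) == 0)
    return(matrix(numeric(0), 0, 0))
  d <- as.matrix(stats::dist(cbind(r$x, r$y)))
  dimnames(d) <- list(r$individual_id, r$individual_id)
  d
}

# Along-bearing and perpendicular coordinates for a compass bearing measured
# in degrees clockwise from north. u increases along the bearing.
.bearing_axes <- function(x, y, bearing) {
  th <- bearing * pi / 180
  list(u = x * sin(th) + y * cos(th),
       v = x * cos(th) - y * sin(th))
}

#' Nearest-neighbor distances in a constant direction
#'
#' For every individual, finds the nearest other individual that lies strictly
#' further along a fixed compass bearing (by default north) and records the
#' full Euclidean distance between the two. Individuals with no other
#' individual further along the bearing (e.g. the northernmost one) produce no
#' record. Pooled over many scenes, these directional nearest-neighbor
#' distances are the raw material for data-driven threshold estimation (see
#' [pool_distances()] and [estimate_thresholds()]).
#'
#' Ties in the along-bearing coordinate are broken by the perpendicular
#' coordinate and then by identifier order, so "further along the bearing" is
#' a strict total order and a scene with all distinct positions yields exactly
#' `n - 1` records.
#'
#' @param scene_obj a `scene` with at least one individual.
#' @param bearing compass bearing in degrees clockwise from north (default 0,
#'   i.e. north).
#' @param body_length_units if `TRUE`, divide each distance by the mean body
#'   length of the pair (requires body lengths on all records; when only one
#'   of a pair has a length, that length is used).
#' @return A data frame with one row per qualifying individual and columns
#'   `scene_id`, `source_id`, `neighbor_id`, `distance_m`, `bearing_deg` and
#'   `source_state`. Empty (zero-row) for a single-individual scene.
#' @examples
#' sc <- scene(c("a", "b"), x = c(0, 0), y = c(0, 10))
#' directional_nn_distances(sc) # a -> b, 10 m
#' @export
directional_nn_distances <- function(scene_obj, bearing = 0,
                                     body_length_units = FALSE) {
  stopifnot(inherits(scene_obj, "scene"))
  r <- scene_obj$records
  n <- nrow(r)
  if (n < 1) stop("scene must contain at least one individual", call. = FALSE)
  if (body_length_units && all(is.na(r$body_length)))
    stop("body_length_units requires body lengths on the records", call. = FALSE)
  empty <- data.frame(scene_id = character(), source_id = character(),
                      neighbor_id = character(), distance_m = numeric(),
                      bearing_deg = numeric(), source_state = character(),
                      stringsAsFactors = FALSE)
  if (n == 1) return(empty)
  ax <- .bearing_axes(r$x, r$y, bearing)
  u <- ax$u; v <- ax$v
  id <- r$individual_id
  out <- vector("list", n)
  for (i in seq_len(n)) {
    # strictly ahead along the bearing, ties broken by v then by id
    ahead <- u > u[i] | (u == u[i] & (v > v[i] | (v == v[i] & id > id[i])))
    if (!any(ahead)) next
    dx <- r$x[ahead] - r$x[i]
    dy <- r$y[ahead] - r$y[i]
    dd <- sqrt(dx^2 + dy^2)
    cand_id <- id[ahead]
    # nearest; exact distance ties broken by identifier order
    ord <- order(dd, cand_id)
    j <- ord[1]
    d <- dd[j]
    if (body_length_units) {
      bl <- c(r$body_length[i], r$body_length[id == cand_id[j]])
      bl <- bl[!is.na(bl)]
      if (!length(bl))
        stop("no body length available for pair ", id[i], "-", cand_id[j],
             call. = FALSE)
      d <- d / mean(bl)
    }
    out[[i]] <- data.frame(scene_id = scene_obj$scene_id, source_id = id[i],
                           neighbor_id = cand_id[j], distance_m = d,
                           bearing_deg = bearing, source_state = r$state[i],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
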