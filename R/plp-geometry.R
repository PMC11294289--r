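# Polygonal language profile geometry: profile construction on a radar
# chart, area, maximal-area axis ordering, triangle decomposition,
# centroid, centroidal distance, and first moment of area.

#' The four elementary verbal operants
#'
#' Canonical condition labels of a verbal operant experimental (VOX)
#' analysis, in the storage order used by [axis_values()].
#'
#' @format Character vector of length 4.
#' @export
vox_operants <- c("tact", "mand", "echoic", "sequelic")

# Canonical radar axis order: +x echoic, +y mand, -x sequelic, -y tact.
# Fixed by the quadrant semantics (Q1 = echoic & mand convergence, Q2 =
# mand & sequelic, Q3 = sequelic & tact, Q4 = tact & echoic).
vox_canonical_axes <- c("echoic", "mand", "sequelic", "tact")

#' Per-operant axis values for one radar profile
#'
#' Bundles the four operant totals (or frequencies) that feed a single
#' polygonal language profile. Values must be finite and non-negative.
#'
#' @param tact,mand,echoic,sequelic Non-negative finite numbers.
#' @return A named numeric vector of class `vox_axis_values`.
#' @examples
#' axis_values(tact = 12, mand = 10, echoic = 12, sequelic = 8)
#' @export
axis_values <- function(tact, mand, echoic, sequelic) {
  v <- c(tact = as.numeric(tact), mand = as.numeric(mand),
         echoic = as.numeric(echoic), sequelic = as.numeric(sequelic))
  if (any(!is.finite(v))) {
    stop("axis values must be finite", call. = FALSE)
  }
  if (any(v < 0)) {
    stop("axis values must be non-negative", call. = FALSE)
  }
  structure(v, class = "vox_axis_values")
}

#' @export
print.vox_axis_values <- function(x, ...) {
  cat("<axis values>", paste(names(x), unclass(x), sep = "=",
                             collapse = "  "), "\n")
  invisible(x)
}

#' Radar chart configuration
#'
#' Fixes the cyclic axis order, the property-space radius `C` (the radius
#' of the circle circumscribing the attainable profile region, used by the
#' first moment of area), and whether profiles keep the canonical semantic
#' axis order or are re-ordered to maximize area.
#'
#' `C` has no default: its correct value is instrument-dependent (e.g. the
#' maximum attainable score per axis), so it must be supplied explicitly
#' wherever the first moment of area is computed.
#'
#' @param property_radius Positive number `C`, or `NULL` if the first
#'   moment of area will not be computed.
#' @param axis_order Cyclic sequence of axis labels; at least 3, default
#'   the canonical VOX order `echoic, mand, sequelic, tact`.
#' @param ordering_mode `"canonical"` (keep semantic positions) or
#'   `"maximize"` (re-order axes to the maximal-area configuration).
#' @return A list of class `vox_radar_config`.
#' @examples
#' radar_config(property_radius = 12)
#' @export
radar_config <- function(property_radius = NULL,
                         axis_order = vox_canonical_axes,
                         ordering_mode = c("canonical", "maximize")) {
  ordering_mode <- match.arg(ordering_mode)
  axis_order <- as.character(axis_order)
  if (length(axis_order) < 3 || anyDuplicated(axis_order)) {
    stop("axis_order must be >= 3 distinct labels", call. = FALSE)
  }
  if (setequal(axis_order, vox_operants) &&
      !identical(sort(axis_order), sort(vox_operants))) {
    stop("axis_order must be a permutation of the operant labels",
         call. = FALSE)
  }
  if (!is.null(property_radius)) {
    property_radius <- as.numeric(property_radius)
    if (!is.finite(property_radius) || property_radius <= 0) {
      stop("property_radius C must be a positive number", call. = FALSE)
    }
  }
  structure(list(axis_order = axis_order,
                 n_axes = length(axis_order),
                 property_radius = property_radius,
                 ordering_mode = ordering_mode),
            class = "vox_radar_config")
}

#' @export
print.vox_radar_config <- function(x, ...) {
  cat("<radar config> axes:", paste(x$axis_order, collapse = " > "),
      " C:", if (is.null(x$property_radius)) "unset" else x$property_radius,
      " ordering:", x$ordering_mode, "\n")
  invisible(x)
}

# Axis values arranged in the config's cyclic order (named numeric).
axis_values_in_order <- function(values, config) {
  v <- unclass(values)
  if (is.null(names(v)) && length(v) == config$n_axes) {
    names(v) <- config$axis_order
  }
  missing <- setdiff(config$axis_order, names(v))
  if (length(missing)) {
    stop("axis values missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v[config$axis_order]
}

# Unit direction of axis i (1-based) among n evenly spaced axes, starting
# on +x and proceeding counterclockwise. cospi/sinpi keep quarter-turn
# coordinates exact for n = 4.
axis_direction <- function(i, n) {
  t <- 2 * (i - 1) / n
  c(cospi(t), sinpi(t))
}

#' Build a polygonal language profile
#'
#' Places each axis value on its radar axis (evenly spaced, starting on +x
#' and proceeding counterclockwise) and connects adjacent vertices into a
#' closed polygon. Under the canonical 4-axis layout the vertices are
#' `(echoic, 0)`, `(0, mand)`, `(-sequelic, 0)`, `(0, -tact)`.
#'
#' @param values An [axis_values()] object, or a named numeric vector
#'   covering `config$axis_order`.
#' @param config A [radar_config()].
#' @return A list of class `vox_plp` with elements `values` (in axis
#'   order), `vertices` (n x 2 matrix), and `config`.
#' @examples
#' build_profile(axis_values(12, 10, 12, 8), radar_config(12))
#' @export
build_profile <- function(values, config = radar_config()) {
  stopifnot(inherits(config, "vox_radar_config"))
  v <- axis_values_in_order(values, config)
  if (any(!is.finite(v))) stop("axis values must be finite", call. = FALSE)
  if (any(v < 0)) stop("axis values must be non-negative", call. = FALSE)
  n <- config$n_axes
  verts <- t(vapply(seq_len(n), function(i) v[i] * axis_direction(i, n),
                    numeric(2)))
  dimnames(verts) <- list(names(v), c("x", "y"))
  if (!is.null(config$property_radius) && max(v) > config$property_radius) {
    warning("axis value ", max(v), " exceeds the property radius C = ",
            config$property_radius, call. = FALSE)
  }
  structure(list(values = v, vertices = verts, config = config),
            class = "vox_plp")
}

#' @export
print.vox_plp <- function(x, ...) {
  cat("<polygonal language profile>", x$config$n_axes, "axes\n")
  print(round(x$vertices, 4))
  invisible(x)
}

#' Area of a polygonal language profile
#'
#' Sums the origin-anchored triangles between adjacent axes:
#' `A = 1/2 * sum_i v_i v_{i+1} sin(2*pi/n)` (cyclic). For four axes this
#' is the quadrant product-sum `1/2 * sum |x_i||y_{i+1}|` and equals the
#' shoelace area of the polygon's vertices.
#'
#' @param plp A `vox_plp` from [build_profile()].
#' @return Non-negative area in squared axis units.
#' @examples
#' polygon_area(build_profile(axis_values(12, 10, 12, 8)))  # 220
#' @export
polygon_area <- function(plp) {
  stopifnot(inherits(plp, "vox_plp"))
  v <- plp$values
  n <- length(v)
  0.5 * sinpi(2 / n) * sum(v * v[c(seq_len(n)[-1], 1)])
}

#' Origin-anchored triangle decomposition of a profile
#'
#' Splits the profile into the n triangles formed by the origin and each
#' adjacent vertex pair (one per quadrant when n = 4). Triangle areas sum
#' to the polygon area and their area-weighted centroids give the polygon
#' centroid.
#'
#' @inheritParams polygon_area
#' @return A tibble with one row per triangle: `triangle`, the two axis
#'   labels it spans, `area`, and signed centroid coordinates `cx`, `cy`.
#' @export
triangle_decomposition <- function(plp) {
  stopifnot(inherits(plp, "vox_plp"))
  n <- nrow(plp$vertices)
  nxt <- c(seq_len(n)[-1], 1)
  v <- plp$values
  verts <- plp$vertices
  tibble::tibble(
    triangle = seq_len(n),
    axis_a = names(v),
    axis_b = names(v)[nxt],
    area = unname(0.5 * sinpi(2 / n) * v * v[nxt]),
    cx = unname((verts[, "x"] + verts[nxt, "x"]) / 3),
    cy = unname((verts[, "y"] + verts[nxt, "y"]) / 3)
  )
}

#' Quadrant convergence areas and shares
#'
#' The region between two adjacent axes depicts convergent multiple
#' control of those two operants; quadrants holding a larger share of the
#' profile indicate stronger convergent control. Under the canonical
#' layout quadrant 1 is echoic-mand convergence, 2 mand-sequelic,
#' 3 sequelic-tact, and 4 tact-echoic.
#'
#' @inheritParams polygon_area
#' @return A tibble with `quadrant`, `operants`, `area`, and `share`
#'   (`area / A`; all `NA` for a degenerate zero-area profile).
#' @examples
#' quadrant_convergence(build_profile(axis_values(12, 10, 12, 8)))
#' @export
quadrant_convergence <- function(plp) {
  tri <- triangle_decomposition(plp)
  total <- sum(tri$area)
  tibble::tibble(
    quadrant = tri$triangle,
    operants = paste(tri$axis_a, tri$axis_b, sep = "&"),
    area = tri$area,
    share = if (total > 0) tri$area / total else rep(NA_real_, nrow(tri))
  )
}

# All permutations of v (rows), in lexicographic order of the input.
permutations <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], permutations(v[-i]), deparse.level = 0)
  }))
}

#' Maximal-area axis ordering
#'
#' Enumerates the `(n-1)!/2` distinct cyclic axis orderings (up to
#' rotation and reflection) and returns one attaining the maximal total
#' area, together with that area (the maximal total area over
#' configurations). Ties are broken deterministically in favour of the
#' ordering lexicographically closest to the canonical order, so equal
#' axis values return the canonical order unchanged.
#'
#' @param values An [axis_values()] object or named non-negative numeric
#'   vector (3 to 10 axes; the search is exhaustive).
#' @param axis_order Canonical cyclic order to enumerate against; default
#'   the VOX order for operant values, otherwise the names of `values`.
#' @return A list with `ordering` (labels), `A_tilde` (maximal area), and
#'   `n_orderings` considered.
#' @examples
#' maximize_area_ordering(axis_values(12, 10, 12, 8))  # A_tilde = 220
#' @export
maximize_area_ordering <- function(values, axis_order = NULL) {
  v <- unclass(values)
  if (is.null(axis_order)) {
    axis_order <- if (setequal(names(v), vox_operants)) vox_canonical_axes
                  else names(v)
  }
  if (is.null(names(v))) names(v) <- axis_order
  v <- v[axis_order]
  n <- length(v)
  if (n < 3 || n > 10) stop("3 to 10 axes supported", call. = FALSE)
  if (any(v < 0) || any(!is.finite(v))) {
    stop("axis values must be finite and non-negative", call. = FALSE)
  }
  rest <- permutations(seq_len(n)[-1])
  keep <- rest[, 1] < rest[, ncol(rest)]   # one representative per reflection
  rest <- rest[keep, , drop = FALSE]
  best_s <- -Inf
  best_idx <- NULL
  for (r in seq_len(nrow(rest))) {
    idx <- c(1L, rest[r, ])
    s <- sum(v[idx] * v[c(idx[-1], idx[1])])
    if (s > best_s + 1e-12) {            # strict: first (lexicographic) wins ties
      best_s <- s
      best_idx <- idx
    }
  }
  list(ordering = axis_order[best_idx],
       A_tilde = 0.5 * sinpi(2 / n) * best_s,
       n_orderings = nrow(rest))
}

#' Centroid of a polygonal language profile
#'
#' Area-weighted mean of the origin-anchored triangle centroids, with
#' signed coordinates; this equals the polygon's true centroid. The
#' centroid is the profile's locus of control: a perfectly balanced
#' repertoire (equal values on all axes) has centroid (0, 0).
#'
#' @inheritParams polygon_area
#' @return Named numeric `c(x, y)`; for a zero-area profile both are `NA`
#'   and the result carries attribute `degenerate = TRUE`.
#' @examples
#' plp_centroid(build_profile(axis_values(12, 10, 12, 8)))  # (1.33, -0.67)
#' @export
plp_centroid <- function(plp) {
  tri <- triangle_decomposition(plp)
  total <- sum(tri$area)
  if (total == 0) {
    return(structure(c(x = NA_real_, y = NA_real_), degenerate = TRUE))
  }
  c(x = sum(tri$area * tri$cx) / total,
    y = sum(tri$area * tri$cy) / total)
}

#' Centroidal distance
#'
#' Euclidean distance from the chart origin to the profile centroid.
#' Smaller distances indicate a more balanced repertoire.
#'
#' @param centroid Named numeric `c(x, y)` from [plp_centroid()].
#' @return Non-negative number; `NA` if the centroid is undefined.
#' @export
centroidal_distance <- function(centroid) {
  if (anyNA(centroid)) return(NA_real_)
  sqrt(sum(centroid[c("x", "y")]^2))
}

#' First moment of area
#'
#' `Q = A * (C - R)`: the profile area weighted by the centroid's depth
#' inside the property space of radius `C`. Combines repertoire size (A)
#' with balance (C - R) into a single scalar.
#'
#' @param area Profile area `A` (>= 0).
#' @param r Centroidal distance `R`; may be `NA` when `area` is 0.
#' @param property_radius The property-space radius `C`; required.
#' @param permissive If `TRUE`, `C < R` produces a warning and a negative
#'   `Q`; otherwise it is an error.
#' @return `Q` in cubed axis units; exactly 0 for a zero-area profile.
#' @examples
#' first_moment(288, 0, 12)  # 3456
#' @export
first_moment <- function(area, r, property_radius, permissive = FALSE) {
  if (missing(property_radius) || is.null(property_radius)) {
    stop("the property radius C is required to compute the first moment ",
         "of area; supply property_radius (e.g. via radar_config())",
         call. = FALSE)
  }
  if (area == 0) return(0)
  if (is.na(r)) stop("centroidal distance is undefined", call. = FALSE)
  if (property_radius < r) {
    msg <- paste0("centroidal distance R = ", signif(r, 6),
                  " exceeds the property radius C = ", property_radius)
    if (!permissive) stop(msg, call. = FALSE)
    warning(msg, "; Q will be negative", call. = FALSE)
  }
  area * (property_radius - r)
}

#' Full shape-descriptor set for one profile
#'
#' Composes the descriptor pipeline: profile construction, area, the
#' maximal-area ordering, triangle-decomposition centroid, centroidal
#' distance, quadrant convergence, and (when `C` is configured) the first
#' moment of area. With `ordering_mode = "maximize"` the axes are first
#' re-ordered to the maximal-area configuration.
#'
#' @param values An [axis_values()] object or named numeric vector.
#' @param config A [radar_config()]. `property_radius` may be `NULL`, in
#'   which case `Q` is `NA` and a note is attached.
#' @param permissive Passed to [first_moment()].
#' @return A `vox_descriptors` object; see [shape_descriptors()].
#' @examples
#' describe_profile(axis_values(12, 10, 12, 8), radar_config(12))
#' @export
describe_profile <- function(values, config = radar_config(),
                             permissive = FALSE) {
  stopifnot(inherits(config, "vox_radar_config"))
  v <- axis_values_in_order(values, config)
  opt <- maximize_area_ordering(v, axis_order = config$axis_order)
  if (config$ordering_mode == "maximize") {
    config$axis_order <- opt$ordering
    v <- v[opt$ordering]
  }
  plp <- build_profile(v, config)
  a <- polygon_area(plp)
  ctr <- plp_centroid(plp)
  r <- centroidal_distance(ctr)
  q <- if (is.null(config$property_radius)) NA_real_
       else first_moment(a, r, config$property_radius, permissive)
  shape_descriptors(area = a, centroid = ctr, r = r, q = q,
                    property_radius = config$property_radius,
                    a_tilde = opt$A_tilde,
                    quadrants = quadrant_convergence(plp),
                    values = v, ordering = config$axis_order,
                    ordering_mode = config$ordering_mode)
}

#' Shape-descriptor record
#'
#' Low-level constructor for a descriptor set. [describe_profile()] is the
#' usual entry point; this constructor also admits records transcribed
#' from published descriptor tables, where only `A`, `R`, `Q` (and
#' possibly the centroid) are known and the underlying axis values are
#' not.
#'
#' @param area Profile area `A`.
#' @param centroid Named numeric `c(x, y)` or `NULL` if unknown.
#' @param r Centroidal distance; defaults to the centroid norm.
#' @param q First moment of area, or `NA`.
#' @param property_radius The `C` used, or `NULL`.
#' @param a_tilde Maximal-area `A` over orderings, or `NA` if unknown.
#' @param quadrants Optional tibble from [quadrant_convergence()].
#' @param values Optional axis values (in ordering).
#' @param ordering Axis ordering the descriptors refer to.
#' @param ordering_mode `"canonical"` or `"maximize"`.
#' @return A list of class `vox_descriptors` with fields `A`, `A_tilde`,
#'   `centroid`, `R`, `Q`, `C`, `quadrants`, `values`, `ordering`.
#' @export
shape_descriptors <- function(area, centroid = NULL, r = NULL, q = NA_real_,
                              property_radius = NULL, a_tilde = NA_real_,
                              quadrants = NULL, values = NULL,
                              ordering = vox_canonical_axes,
                              ordering_mode = "canonical") {
  if (is.null(centroid)) centroid <- c(x = NA_real_, y = NA_real_)
  if (is.null(r)) r <- centroidal_distance(centroid)
  structure(list(A = as.numeric(area), A_tilde = as.numeric(a_tilde),
                 centroid = centroid, R = as.numeric(r), Q = as.numeric(q),
                 C = property_radius, quadrants = quadrants,
                 values = values, ordering = ordering,
                 ordering_mode = ordering_mode),
            class = "vox_descriptors")
}

#' @export
print.vox_descriptors <- function(x, digits = 2, ...) {
  cat("<shape descriptors>\n")
  cat(sprintf("  A  = %.*f   (A~ = %.*f)\n", digits, x$A, digits, x$A_tilde))
  if (anyNA(x$centroid)) {
    cat("  centroid undefined (zero-area profile)\n")
  } else {
    cat(sprintf("  centroid = (%.*f, %.*f)   R = %.*f\n",
                digits, x$centroid[["x"]], digits, x$centroid[["y"]],
                digits, x$R))
  }
  cat(sprintf("  Q  = %s   (C = %s)\n",
              if (is.na(x$Q)) "NA" else sprintf("%.*f", digits, x$Q),
              if (is.null(x$C)) "unset" else x$C))
  invisible(x)
}
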