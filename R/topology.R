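#' @useDynLib tautopo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

check_topology_curve <- function(x, min_vertices = 2L, arg = "curve") {
  if (!inherits(x, "polygonal_curve")) {
    stop(sprintf("`%s` must be a polygonal_curve", arg))
  }
  if (isTRUE(attr(x, "degenerate")) || n_vertices(x) < min_vertices) {
    stop(sprintf("`%s` is degenerate: topological measures need >= %d vertices",
                 arg, min_vertices))
  }
  invisible(x)
}

#' Gauss linking integral of two open or closed curves
#'
#' The linking number Lk of two disjoint oriented polygonal curves, computed
#' as the exact sum over all segment pairs of the signed solid-angle (Gauss
#' integral) contribution. For open curves this is a real number; it equals
#' the average over all projection directions of half the signed sum of
#' inter-curve crossings.
#'
#' @param c1,c2 `polygonal_curve` objects with disjoint vertex sets.
#' @return The linking number (double).
#' @seealso [writhe()], [linking_projection_estimate()] for the
#'   sampling-based crossing-count route.
#' @examples
#' a <- polygonal_curve(cbind(cos(seq(0, 2 * pi, length.out = 40)[-40]),
#'                            sin(seq(0, 2 * pi, length.out = 40)[-40]), 0),
#'                      closed = TRUE)
#' b <- polygonal_curve(cbind(1 + cos(seq(0, 2 * pi, length.out = 40)[-40]), 0,
#'                            sin(seq(0, 2 * pi, length.out = 40)[-40])),
#'                      closed = TRUE)
#' round(gauss_linking(a, b), 6)  # Hopf link: +/- 1
#' @export
gauss_linking <- function(c1, c2) {
  check_topology_curve(c1, 2L, "c1")
  check_topology_curve(c2, 2L, "c2")
  if (curves_touch(c1, c2)) {
    stop("curves share a point: the Gauss integral is singular")
  }
  cpp_gauss_linking(c1$vertices, c2$vertices, c1$closed, c2$closed)
}

# Do two curves have (numerically) coincident vertices?
curves_touch <- function(c1, c2, tol = 1e-9) {
  v1 <- c1$vertices; v2 <- c2$vertices
  for (i in seq_len(nrow(v1))) {
    d2 <- (v2[, 1] - v1[i, 1])^2 + (v2[, 2] - v1[i, 2])^2 + (v2[, 3] - v1[i, 3])^2
    if (any(d2 <= tol^2)) return(TRUE)
  }
  FALSE
}

#' Writhe of a polygonal curve
#'
#' The self-linking analogue of the Gauss integral: the exact sum over all
#' non-adjacent segment pairs of twice the per-pair solid-angle contribution,
#' so that the writhe equals the average over all projection directions of
#' the signed sum of self-crossings. The sign reflects handedness: negative
#' writhe indicates a left-handed conformation.
#'
#' @param c A `polygonal_curve` with at least 3 vertices.
#' @return The writhe (double). A planar curve has writhe 0.
#' @export
writhe <- function(c) {
  check_topology_curve(c, 3L, "c")
  cpp_writhe(c$vertices, c$closed)
}

#' Sign of a diagram crossing
#'
#' Right-handed crossings are +1, left-handed -1: with the over-strand
#' direction `u` and under-strand direction `v`, the sign is the sign of
#' `(u x v) . xi` where `xi` is the viewing direction. An over-strand along
#' +x above an under-strand along +y, viewed from +z, is positive.
#'
#' @param over_vector,under_vector 3-D direction vectors of the over and
#'   under strands.
#' @param viewing_direction Unit 3-vector of the projection direction.
#' @return `+1` or `-1`.
#' @export
crossing_sign <- function(over_vector, under_vector, viewing_direction) {
  u <- as.double(over_vector); v <- as.double(under_vector)
  xi <- as.double(viewing_direction)
  xi <- xi / sqrt(sum(xi^2))
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sum(cr * xi)
  scale <- sqrt(sum(u^2)) * sqrt(sum(v^2))
  if (abs(s) <= 1e-12 * scale) {
    stop("degenerate projection: projected strands are parallel")
  }
  if (s > 0) 1 else -1
}

#' Crossing diagram of a projection
#'
#' Projects one curve (self-diagram) or two curves (inter-crossings only)
#' along a direction and records every transverse crossing with its sign and
#' over/under assignment (the strand closer to the viewer, i.e. with the
#' larger coordinate along the direction, is "over"). Self-diagrams exclude
#' adjacent-edge contacts. Non-generic projections (parallel projected edges
#' in contact, endpoint-grazing crossings, depth ties) raise a condition of
#' class `tautopo_degenerate_projection`; callers resample the direction.
#'
#' @param c1 A `polygonal_curve`.
#' @param c2 Optional second `polygonal_curve`; when given only inter-curve
#'   crossings are recorded.
#' @param direction Projection direction (3-vector, normalized internally).
#' @param eps Relative tolerance below which projected edges count as
#'   parallel.
#' @return A `crossing_diagram`: list with `direction`, `crossings` (data
#'   frame with over/under edge indices, sign, edge parameters and
#'   along-curve positions) and `source` (`"self"` or `"pair"`).
#' @export
project_diagram <- function(c1, c2 = NULL, direction, eps = 1e-12) {
  check_topology_curve(c1, 2L, "c1")
  direction <- as.double(direction)
  direction <- direction / sqrt(sum(direction^2))
  if (is.null(c2)) {
    res <- cpp_project_self(c1$vertices, c1$closed, direction, eps)
  } else {
    check_topology_curve(c2, 2L, "c2")
    res <- cpp_project_pair(c1$vertices, c1$closed, c2$vertices, c2$closed,
                            direction, eps)
  }
  if (!isTRUE(res$ok)) {
    stop(structure(class = c("tautopo_degenerate_projection", "error",
                             "condition"),
                   list(message = "non-generic projection: resample the direction",
                        call = sys.call())))
  }
  structure(list(direction = direction,
                 crossings = as.data.frame(res$crossings),
                 source = if (is.null(c2)) "self" else "pair"),
            class = "crossing_diagram")
}

#' @export
print.crossing_diagram <- function(x, ...) {
  cat(sprintf("<crossing_diagram> %s, %d crossings, direction (%.3f, %.3f, %.3f)\n",
              x$source, nrow(x$crossings),
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Per-diagram second Vassiliev value
#'
#' Half the sum, over ordered point four-tuples `j1 < j2 < j3 < j4` along the
#' curve that form two interleaved crossings (`j1, j3` one crossing, `j2, j4`
#' the other) with alternating over/under pattern (the strand status at `j1`
#' differs from that at `j2`), of the product of the two crossing signs. For
#' a closed curve this is the second Vassiliev invariant of the knot and is
#' identical in every generic projection; for an open curve it depends on the
#' projection and sphere-averaging it gives the second Vassiliev measure.
#'
#' @param d A self-`crossing_diagram` from [project_diagram()].
#' @return The diagram value (multiple of 0.5). An empty or single-crossing
#'   diagram gives 0.
#' @export
diagram_v2 <- function(d) {
  stopifnot(inherits(d, "crossing_diagram"))
  if (d$source != "self") {
    stop("diagram_v2 is defined for the diagram of a single curve")
  }
  cs <- d$crossings
  m <- nrow(cs)
  if (m < 2L) return(0)
  # over/under status of the passage at pos1 for each crossing
  over1 <- cs$pos1 == (cs$over_edge - 1 + cs$over_param)
  total <- 0
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      a1 <- cs$pos1[i]; a2 <- cs$pos2[i]
      b1 <- cs$pos1[j]; b2 <- cs$pos2[j]
      inter <- (a1 < b1 && b1 < a2 && a2 < b2) ||
               (b1 < a1 && a1 < b2 && b2 < a2)
      if (!inter) next
      if (a1 < b1) {
        j1_over <- over1[i]; j2_over <- over1[j]
      } else {
        j1_over <- over1[j]; j2_over <- over1[i]
      }
      if (j1_over != j2_over) total <- total + cs$sign[i] * cs$sign[j]
    }
  }
  0.5 * total
}

#' Projection-sampled second Vassiliev measure
#'
#' Mean of the per-diagram value ([diagram_v2()]) over directions sampled
#' uniformly on the sphere. Endpoints of open curves are left free (knotoid
#' convention; no closure segment is added). Degenerate projections are
#' resampled and counted.
#'
#' @param c A `polygonal_curve`.
#' @param n_projections Number of sampled directions (the reference analyses
#'   use 1e5).
#' @param seed Integer seed; set for reproducibility.
#' @param keep_values Keep the per-projection values and directions (needed
#'   by [knotoid_flag()]).
#' @param eps Parallel-edge tolerance passed to the diagram builder.
#' @return A `vassiliev2_result`: list with `estimate`, `se` (Monte-Carlo
#'   standard error), `n_projections`, `n_degenerate`, `seed`, and when
#'   requested `values` / `directions`.
#' @export
vassiliev2 <- function(c, n_projections = 1e5, seed = NULL,
                       keep_values = FALSE, eps = 1e-12) {
  check_topology_curve(c, 3L, "c")
  n_projections <- as.integer(n_projections)
  stopifnot(n_projections >= 1L)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_vassiliev2(c$vertices, c$closed, n_projections, eps, keep_values)
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(res) <- "vassiliev2_result"
  res
}

#' @export
print.vassiliev2_result <- function(x, ...) {
  cat(sprintf("second Vassiliev measure: %.6g (MC se %.2g, %d projections, %d degenerate resamples)\n",
              x$estimate, x$se, x$n_projections, x$n_degenerate))
  invisible(x)
}

#' Monte-Carlo projection estimates of linking number and writhe
#'
#' The diagrammatic route to Lk and Wr: sample projection directions
#' uniformly on the sphere and average half the signed inter-crossing sum
#' (linking) or the signed self-crossing sum (writhe). These estimators
#' converge to the exact segment-pair integrals [gauss_linking()] and
#' [writhe()] and serve as an independent cross-check of them.
#'
#' @param c1,c2,c `polygonal_curve` inputs.
#' @param n_projections Number of sampled directions.
#' @param seed Integer seed.
#' @param eps Parallel-edge tolerance.
#' @return List with `estimate`, `se`, `n_projections`, `n_degenerate`.
#' @export
linking_projection_estimate <- function(c1, c2, n_projections = 1e4,
                                        seed = NULL, eps = 1e-12) {
  check_topology_curve(c1, 2L, "c1")
  check_topology_curve(c2, 2L, "c2")
  if (!is.null(seed)) set.seed(seed)
  cpp_linking_mc(c1$vertices, c1$closed, c2$vertices, c2$closed,
                 as.integer(n_projections), eps)
}

#' @rdname linking_projection_estimate
#' @export
writhe_projection_estimate <- function(c, n_projections = 1e4, seed = NULL,
                                       eps = 1e-12) {
  check_topology_curve(c, 3L, "c")
  if (!is.null(seed)) set.seed(seed)
  cpp_writhe_mc(c$vertices, c$closed, as.integer(n_projections), eps)
}

# Per-edge-pair Gauss contributions of one curve with itself, as an
# (n-1) x (n-1) matrix; fragment-vs-fragment linking numbers are block sums.
segment_gauss_matrix <- function(f) {
  v <- f$backbone$vertices
  n <- nrow(v)
  e <- n - 1L
  g <- matrix(0, e, e)
  for (i in seq_len(e - 1L)) {
    for (j in seq.int(i + 1L, e)) {
      g[i, j] <- cpp_gauss_linking(v[i:(i + 1L), , drop = FALSE],
                                   v[j:(j + 1L), , drop = FALSE],
                                   FALSE, FALSE)
      g[j, i] <- g[i, j]
    }
  }
  g
}
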