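#' Discretized circular helix
#'
#' Open helical polygonal curve, the canonical fixture with known non-zero
#' writhe; mirroring it negates the writhe.
#'
#' @param turns Number of full turns (> 0, fractional allowed).
#' @param radius Helix radius (Angstrom).
#' @param pitch Rise per full turn (Angstrom).
#' @param points_per_turn Vertices per turn.
#' @param handedness `"right"` or `"left"`.
#' @return An open `polygonal_curve`.
#' @examples
#' h <- make_helix(4, radius = 2.3, pitch = 5.4)
#' writhe(h)
#' @export
make_helix <- function(turns, radius = 1, pitch = 1, points_per_turn = 20,
                       handedness = c("right", "left")) {
  stopifnot(turns > 0, radius > 0)
  handedness <- match.arg(handedness)
  n <- max(3L, ceiling(points_per_turn * turns) + 1L)
  t <- seq(0, 2 * pi * turns, length.out = n)
  sgn <- if (handedness == "right") 1 else -1
  polygonal_curve(cbind(radius * cos(t), sgn * radius * sin(t),
                        pitch * t / (2 * pi)),
                  label = sprintf("helix_%s_%g_turns", handedness, turns))
}

#' Closed polygonal knots with known second Vassiliev invariant
#'
#' Standard parametric realizations: the (2,3) torus knot (trefoil, v2 = 1),
#' the figure-eight knot (v2 = -1), the 5_2 knot as the Lissajous curve with
#' frequencies (3, 2, 7) and phases (0.7, 0.2, 0) (v2 = 2), and a planar
#' circle (unknot, v2 = 0). With `verify = TRUE` the generator self-checks
#' its knot type by requiring the per-diagram value to equal the knot's known
#' invariant across 10 random generic projections.
#'
#' @param kind One of `"trefoil"`, `"figure8"`, `"5_2"`, `"unknot"`.
#' @param n_vertices Number of polygon vertices (default depends on kind).
#' @param verify Self-check projection invariance of the diagram value.
#' @return A closed `polygonal_curve`.
#' @examples
#' k <- make_knot("trefoil")
#' d <- project_diagram(k, direction = c(0.2, 0.3, 1))
#' diagram_v2(d)  # 1
#' @export
make_knot <- function(kind = c("trefoil", "figure8", "5_2", "unknot"),
                      n_vertices = NULL, verify = FALSE) {
  kind <- match.arg(kind)
  if (is.null(n_vertices)) {
    n_vertices <- switch(kind, trefoil = 61L, figure8 = 80L,
                         `5_2` = 160L, unknot = 24L)
  }
  n_vertices <- as.integer(n_vertices)
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  v <- switch(kind,
    trefoil = cbind((2 + cos(3 * t)) * cos(2 * t),
                    (2 + cos(3 * t)) * sin(2 * t),
                    sin(3 * t)),
    figure8 = cbind((2 + cos(2 * t)) * cos(3 * t),
                    (2 + cos(2 * t)) * sin(3 * t),
                    sin(4 * t)),
    `5_2` = cbind(cos(3 * t + 0.7), cos(2 * t + 0.2), cos(7 * t)),
    unknot = cbind(cos(t), sin(t), 0))
  k <- polygonal_curve(v, closed = TRUE, label = kind)
  if (verify) {
    target <- switch(kind, trefoil = 1, figure8 = -1, `5_2` = 2, unknot = 0)
    vals <- vapply(seq_len(10L), function(i) {
      repeat {
        d <- stats::rnorm(3)
        val <- tryCatch(diagram_v2(project_diagram(k, direction = d)),
                        tautopo_degenerate_projection = function(e) NULL)
        if (!is.null(val)) return(val)
      }
    }, numeric(1))
    if (!all(vals == target)) {
      stop(sprintf("discretization too coarse for '%s': diagram values (%s) differ from the invariant %g",
                   kind, paste(unique(vals), collapse = ", "), target))
    }
  }
  k
}

#' The K2_1 knotoid as an open polygonal curve
#'
#' Seven-vertex open curve whose projection along the canonical direction
#' (stored in `attr(, "canonical_direction")`, the +z axis) is the standard
#' two-crossing K2_1 knotoid diagram: one alternating interleaved crossing
#' pair, both crossings positive, per-diagram second Vassiliev value exactly
#' 0.5. Other directions see simpler diagrams, so the sphere-averaged measure
#' lies strictly between 0 and 0.5.
#'
#' @return An open `polygonal_curve` with a `canonical_direction` attribute.
#' @examples
#' k <- make_k21_knotoid()
#' diagram_v2(project_diagram(k, direction = attr(k, "canonical_direction")))
#' @export
make_k21_knotoid <- function() {
  v <- rbind(c(0, -2, 0),
             c(0,  2, 0),
             c(2,  2, -1),
             c(2, -1, -1),
             c(-2, -1, -1),
             c(-2,  1, 1),
             c(1,  1, 1))
  out <- polygonal_curve(v, closed = FALSE, label = "K2_1")
  attr(out, "canonical_direction") <- c(0, 0, 1)
  out
}

# Default protofilament fold used by make_synthetic_fibril: a flat open
# C-shaped arc with ~4.8 A CA spacing, emulating the in-plane cross section
# of an amyloid rung. The arc keeps non-consecutive residues well separated
# so that side-chain push-offs link only with their own backbone stretch.
default_fold_curve <- function(n_residues = 73L, radius = 66) {
  n <- as.integer(n_residues)
  theta <- (seq_len(n) - 1) * 4.8 / radius
  polygonal_curve(cbind(radius * cos(theta), radius * sin(theta), 0),
                  label = "synthetic_fold")
}

#' Write a synthetic cross-beta fibril as a PDB file
#'
#' Stacks copies of a planar protofilament fold along z with the canonical
#' cross-beta rise (4.7 Angstrom) and a per-rung twist, and places one
#' side-chain heavy atom (CB of an alanine-like residue) per residue so that
#' the push-off frame rotates a prescribed number of times around the
#' backbone. The construction ground truth: `sidechain_turns` right-handed
#' turns give a backbone/push-off ribbon linking number close to
#' `sidechain_turns`, and an untwisted stack of planar rungs has
#' stacked-filament linking 0.
#'
#' @param path Output PDB path.
#' @param n_rungs Number of stacked filament copies (chains A, B, ...).
#' @param rise Axial rise per rung in Angstrom.
#' @param twist_deg Rotation about the fibril axis per rung, degrees.
#' @param fold_curve The rung fold as an open planar `polygonal_curve`
#'   (default: a flat 73-residue C-shaped arc).
#' @param sidechain_turns Total right-handed turns of the side-chain
#'   direction about the backbone over the filament length.
#' @param sidechain_dist CB distance from CA in Angstrom (1.5 matches a real beta carbon).
#' @param gly_every Every `gly_every`-th residue is written as glycine
#'   (no side-chain atom); 0 disables.
#' @param jitter Gaussian coordinate noise (Angstrom, applied to the fold
#'   once, shared by all rungs).
#' @param seed Integer seed for the jitter.
#' @return `path`, invisibly. A manifest attribute records the parameters.
#' @export
make_synthetic_fibril <- function(path, n_rungs = 3, rise = 4.7,
                                  twist_deg = -1, fold_curve = NULL,
                                  sidechain_turns = 0, sidechain_dist = 1.5,
                                  gly_every = 0, jitter = 0, seed = 1) {
  stopifnot(n_rungs >= 1)
  if (is.null(fold_curve)) fold_curve <- default_fold_curve()
  stopifnot(inherits(fold_curve, "polygonal_curve"))
  v <- fold_curve$vertices
  n <- nrow(v)
  if (jitter > 0) {
    set.seed(as.integer(seed))
    v <- v + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
  }
  # side-chain placement in the twist-free frame of the (near-planar) fold:
  # n1 = z, n2 = tangent x z, rotating by 2*pi*sidechain_turns along the chain
  tang <- rbind(v[2, ] - v[1, ],
                (v[pmin(n, 2:n + 1), , drop = FALSE] -
                   v[pmax(1, 2:n - 1), , drop = FALSE]))
  tang <- tang / sqrt(rowSums(tang^2))
  zhat <- c(0, 0, 1)
  n2 <- cbind(tang[, 2] * zhat[3] - tang[, 3] * zhat[2],
              tang[, 3] * zhat[1] - tang[, 1] * zhat[3],
              tang[, 1] * zhat[2] - tang[, 2] * zhat[1])
  n2 <- n2 / sqrt(rowSums(n2^2))
  theta <- 2 * pi * sidechain_turns * (seq_len(n) - 1) / (n - 1)
  cb <- v + sidechain_dist *
    (cos(theta) * matrix(zhat, n, 3, byrow = TRUE) + sin(theta) * n2)

  is_gly <- if (gly_every > 0) (seq_len(n) %% gly_every) == 0L else rep(FALSE, n)

  xyz <- NULL; resno <- NULL; resid <- NULL; elety <- NULL
  chain <- NULL; elesy <- NULL
  for (r in seq_len(n_rungs)) {
    ang <- (r - 1) * twist_deg * pi / 180
    rot <- rbind(c(cos(ang), -sin(ang), 0),
                 c(sin(ang), cos(ang), 0),
                 c(0, 0, 1))
    shift <- c(0, 0, (r - 1) * rise)
    ca_r <- sweep(v %*% t(rot), 2, shift, "+")
    cb_r <- sweep(cb %*% t(rot), 2, shift, "+")
    for (i in seq_len(n)) {
      xyz <- c(xyz, ca_r[i, ])
      resno <- c(resno, i)
      resid <- c(resid, if (is_gly[i]) "GLY" else "ALA")
      elety <- c(elety, "CA"); elesy <- c(elesy, "C")
      chain <- c(chain, LETTERS[r])
      if (!is_gly[i]) {
        xyz <- c(xyz, cb_r[i, ])
        resno <- c(resno, i)
        resid <- c(resid, "ALA")
        elety <- c(elety, "CB"); elesy <- c(elesy, "C")
        chain <- c(chain, LETTERS[r])
      }
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = chain, elesy = elesy,
                   eleno = seq_along(resno))
  attr(path, "manifest") <- list(n_rungs = n_rungs, rise = rise,
                                 twist_deg = twist_deg,
                                 n_residues = n,
                                 sidechain_turns = sidechain_turns,
                                 sidechain_dist = sidechain_dist,
                                 gly_every = gly_every,
                                 jitter = jitter, seed = seed)
  invisible(path)
}
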