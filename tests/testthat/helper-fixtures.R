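# Shared fixtures, all generated in code.

# Random open polygonal curve with bounded step lengths.
random_curve <- function(n, seed, scale = 2) {
  set.seed(seed)
  start <- stats::rnorm(3, sd = 3)
  steps <- matrix(stats::rnorm(3 * (n - 1)), n - 1, 3)
  polygonal_curve(rbind(start,
                        sweep(apply(steps * scale / 2, 2, cumsum), 2, start, "+")))
}

# Two nearly-closed circular arcs arranged as a Hopf link.
hopf_arcs <- function(degrees = 359.9, n = 120) {
  t <- seq(0, degrees / 180 * pi, length.out = n)
  a <- polygonal_curve(cbind(cos(t), sin(t), 0))
  b <- polygonal_curve(cbind(1 + cos(t), 0, sin(t)))
  list(a = a, b = b)
}

# A generic random projection direction that yields a valid diagram.
generic_diagram <- function(curve, seed) {
  set.seed(seed)
  repeat {
    d <- stats::rnorm(3)
    res <- tryCatch(project_diagram(curve, direction = d),
                    tautopo_degenerate_projection = function(e) NULL)
    if (!is.null(res)) return(res)
  }
}

# Random rigid motion (rotation + translation) applied to a curve.
rigid_motion <- function(curve, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- stats::rnorm(3, sd = 10)
  polygonal_curve(sweep(curve$vertices %*% q, 2, shift, "+"),
                  closed = curve$closed, label = curve$label)
}

# A filament with tau-like residue numbering wrapped around a helix,
# covering all four repeats and the C-terminal region.
tau_numbered_helix <- function(first = 270, turns = 6) {
  h <- make_helix(turns, radius = 8, pitch = 12, points_per_turn = 20)
  filament_model(h, residue_numbers = seq(first, length.out = n_vertices(h)),
                 accession = "synthetic_helix")
}
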