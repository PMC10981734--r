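test_that("crossing sign convention is right-handed positive", {
  # over along +x above under along +y, viewed from +z: positive
  expect_equal(crossing_sign(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 1)
  # reversing one strand's orientation negates the sign
  expect_equal(crossing_sign(c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1)), -1)
  expect_equal(crossing_sign(c(1, 0, 0), c(0, -1, 0), c(0, 0, 1)), -1)
  # reversing both restores it
  expect_equal(crossing_sign(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1)), 1)
  # parallel projected strands are a degenerate-projection signal
  expect_error(crossing_sign(c(1, 0, 0), c(1, 0, 5), c(0, 0, 1)), "parallel")
})

test_that("crossing sign agrees with the sign of the exact pair integral", {
  # two skew segments with a single crossing seen from +z
  over <- polygonal_curve(rbind(c(-1, 0, 1), c(1, 0, 1)))
  under <- polygonal_curve(rbind(c(0, -1, 0), c(0, 1, 0)))
  s <- crossing_sign(c(2, 0, 0), c(0, 2, 0), c(0, 0, 1))
  expect_equal(sign(gauss_linking(over, under)), s)
})

test_that("Hopf-linked near-closed arcs have |Lk| within 0.01 of 1", {
  arcs <- hopf_arcs(359.9)
  expect_equal(abs(gauss_linking(arcs$a, arcs$b)), 1, tolerance = 0.01)
})

test_that("coplanar configurations have zero linking and writhe", {
  t <- seq(0, 2 * pi, length.out = 25)[-25]
  a <- polygonal_curve(cbind(cos(t), sin(t), 0), closed = TRUE)
  b <- polygonal_curve(cbind(3 + cos(t), sin(t), 0), closed = TRUE)
  expect_equal(gauss_linking(a, b), 0, tolerance = 1e-12)
  set.seed(11)
  flat <- polygonal_curve(cbind(stats::rnorm(15), stats::rnorm(15), 0))
  expect_equal(writhe(flat), 0, tolerance = 1e-12)
})

test_that("linking is symmetric, orientation-antisymmetric, mirror-negated", {
  c1 <- random_curve(14, seed = 21)
  c2 <- random_curve(14, seed = 22)
  lk <- gauss_linking(c1, c2)
  expect_equal(gauss_linking(c2, c1), lk, tolerance = 1e-12)
  expect_equal(gauss_linking(reverse_curve(c1), c2), -lk, tolerance = 1e-12)
  expect_equal(gauss_linking(c1, reverse_curve(c2)), -lk, tolerance = 1e-12)
  expect_equal(gauss_linking(reverse_curve(c1), reverse_curve(c2)), lk,
               tolerance = 1e-12)
  expect_equal(gauss_linking(mirror_curve(c1), mirror_curve(c2)), -lk,
               tolerance = 1e-12)
  wr <- writhe(c1)
  expect_equal(writhe(reverse_curve(c1)), wr, tolerance = 1e-12)
  expect_equal(writhe(mirror_curve(c1)), -wr, tolerance = 1e-12)
})

test_that("touching curves raise a singularity error", {
  c1 <- polygonal_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  c2 <- polygonal_curve(rbind(c(1, 0, 0), c(2, 5, 1)))
  expect_error(gauss_linking(c1, c2), "singular")
})

test_that("Lk and Wr are continuous: tiny perturbations give tiny changes", {
  c1 <- random_curve(18, seed = 31)
  c2 <- random_curve(18, seed = 32)
  lk0 <- gauss_linking(c1, c2)
  wr0 <- writhe(c1)
  set.seed(33)
  delta <- 1e-6
  p1 <- polygonal_curve(c1$vertices + matrix(stats::runif(54, -delta, delta), 18, 3))
  p2 <- polygonal_curve(c2$vertices + matrix(stats::runif(54, -delta, delta), 18, 3))
  expect_lt(abs(gauss_linking(p1, p2) - lk0), 1e-4)
  expect_lt(abs(writhe(p1) - wr0), 1e-4)
})

test_that("rigid motion and uniform scaling leave the measures unchanged", {
  c1 <- random_curve(16, seed = 41)
  c2 <- random_curve(16, seed = 42)
  m1 <- rigid_motion(c1, seed = 43)
  m2 <- polygonal_curve(rigid_motion(c2, seed = 43)$vertices)
  # same motion applied to both curves
  set.seed(43)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- stats::rnorm(3, sd = 10)
  move <- function(cc, s = 1) {
    polygonal_curve(sweep(s * cc$vertices %*% q, 2, shift, "+"),
                    closed = cc$closed)
  }
  for (s in c(1, 2, 0.37)) {
    expect_equal(gauss_linking(move(c1, s), move(c2, s)),
                 gauss_linking(c1, c2), tolerance = 1e-8)
    expect_equal(writhe(move(c1, s)), writhe(c1), tolerance = 1e-8)
  }
})

test_that("projection diagrams have the expected crossing structure", {
  straight <- polygonal_curve(rbind(c(0, 0, 0), c(1, 0, 1), c(2, 0, 0)))
  d <- project_diagram(straight, direction = c(0.1, 0.2, 1))
  expect_equal(nrow(d$crossings), 0L)
  expect_equal(diagram_v2(d), 0)

  tre <- make_knot("trefoil")
  dt <- project_diagram(tre, direction = c(0, 0, 1))
  expect_equal(nrow(dt$crossings), 3L)
  expect_equal(length(unique(dt$crossings$sign)), 1L)

  k21 <- make_k21_knotoid()
  dk <- project_diagram(k21, direction = attr(k21, "canonical_direction"))
  expect_equal(nrow(dk$crossings), 2L)
  expect_equal(dk$crossings$sign, c(1, 1))
})

test_that("closed-knot diagram values are projection invariants", {
  expected <- c(trefoil = 1, figure8 = -1, `5_2` = 2, unknot = 0)
  for (kind in names(expected)) {
    kn <- make_knot(kind)
    vals <- vapply(seq_len(10), function(i) {
      diagram_v2(generic_diagram(kn, seed = 1000 + 17 * i))
    }, numeric(1))
    expect_equal(unique(vals), unname(expected[[kind]]),
                 info = paste("knot:", kind))
  }
})

test_that("sphere-averaged v2 of closed knots matches the invariant", {
  tre <- make_knot("trefoil")
  v <- vassiliev2(tre, n_projections = 3000, seed = 7)
  expect_equal(v$estimate, 1, tolerance = 1e-9)  # every projection equal
  expect_equal(v$se, 0, tolerance = 1e-12)
})

test_that("v2 of an open curve depends on projection but averages smoothly", {
  k21 <- make_k21_knotoid()
  v <- vassiliev2(k21, n_projections = 3000, seed = 9, keep_values = TRUE)
  expect_true(all(v$values %in% c(0, 0.5)))
  expect_gt(v$estimate, 0)
  expect_lt(v$estimate, 0.5)
  # mirror image: per-diagram values of the canonical view keep value 0.5
  mk <- mirror_curve(k21)
  dm <- project_diagram(mk, direction = c(0, 0, -1))
  expect_equal(diagram_v2(dm), 0.5)
})

test_that("straight and convex-planar curves have zero Vassiliev measure", {
  arc <- polygonal_curve(cbind(cos(seq(0, 2, length.out = 12)),
                               sin(seq(0, 2, length.out = 12)), 0))
  v <- vassiliev2(arc, n_projections = 300, seed = 3)
  expect_equal(v$estimate, 0)
})

test_that("exact Lk/Wr agree with projection oracles on random fixtures", {
  # small version of the oracle-equivalence suite (full run in acceptance)
  for (i in 1:3) {
    c1 <- random_curve(12 + i, seed = 100 + i)
    c2 <- random_curve(12 + i, seed = 200 + i)
    mc <- linking_projection_estimate(c1, c2, n_projections = 20000,
                                      seed = 300 + i)
    expect_lt(abs(mc$estimate - gauss_linking(c1, c2)),
              3 * max(mc$se, 1e-12))
    wm <- writhe_projection_estimate(c1, n_projections = 20000,
                                     seed = 400 + i)
    expect_lt(abs(wm$estimate - writhe(c1)), 3 * max(wm$se, 1e-12))
  }
})

test_that("vassiliev2 is seed-reproducible", {
  c1 <- random_curve(15, seed = 51)
  a <- vassiliev2(c1, 500, seed = 99)
  b <- vassiliev2(c1, 500, seed = 99)
  expect_identical(a$estimate, b$estimate)
})
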