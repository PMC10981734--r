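test_that("repeat linking covers the tabulated pairs and propagates ND", {
  f <- tau_numbered_helix(first = 306)   # no R1/R2 resolved
  rt <- repeat_linking(f)
  expect_equal(nrow(rt), 9L)
  nd <- is.na(rt$lk)
  expect_true(all(nd[rt$a %in% c("R1", "R2")]))
  expect_true(all(!nd[rt$a == "R3" | rt$a == "R4"]))
})

test_that("coplanar repeats have zero pairwise linking", {
  t <- seq(0, 6 * pi, length.out = 140)
  flat <- polygonal_curve(cbind(t * cos(t), t * sin(t), 0))
  f <- filament_model(flat, residue_numbers = seq(250, length.out = 140))
  rt <- repeat_linking(f)
  expect_true(all(abs(rt$lk[!is.na(rt$lk)]) < 1e-12))
})

test_that("sign tuples encode signs, treat zero as ND, flip under mirror", {
  f <- tau_numbered_helix()
  rt <- repeat_linking(f)
  st <- sign_tuple(rt)
  expect_true(all(unclass(st) %in% c("+", "-", "ND")))
  fm <- filament_model(mirror_curve(f$backbone),
                       residue_numbers = f$residue_numbers)
  stm <- sign_tuple(repeat_linking(fm))
  flip <- c("+" = "-", "-" = "+", "ND" = "ND")
  expect_equal(unname(unclass(stm)), unname(flip[unclass(st)]))
  # exact zero maps to ND
  rt0 <- structure(data.frame(a = repeat_pairs()[, 1], b = repeat_pairs()[, 2],
                              lk = 0),
                   class = c("repeat_link_table", "data.frame"))
  expect_true(all(unclass(sign_tuple(rt0)) == "ND"))
})

test_that("tuple distance is a Hamming count with ND semantics", {
  mk <- function(x) structure(stats::setNames(x, paste0("(p", seq_along(x), ")")),
                              class = "sign_tuple")
  expect_equal(tuple_distance(mk(rep("+", 6)), mk(rep("+", 6))), 0)
  expect_equal(tuple_distance(mk(rep("+", 6)), mk(rep("-", 6))), 6)
  expect_equal(tuple_distance(mk(c("+", "ND")), mk(c("+", "-"))), 1)
  expect_equal(tuple_distance(mk(c("ND", "ND")), mk(c("ND", "ND"))), 0)
  # different arity: missing positions are ND-padded
  a <- structure(c("(x)" = "+"), class = "sign_tuple")
  b <- structure(c("(x)" = "+", "(y)" = "-"), class = "sign_tuple")
  expect_equal(tuple_distance(a, b), 1)
})

test_that("published repeat-sign tuples reproduce the reported contrasts", {
  ids <- tau_global_metrics()$id
  tuples <- lapply(ids, function(id) {
    sign_tuple(tautopo:::published_repeat_table(id))
  })
  names(tuples) <- ids
  # AD, PART and CTE share one tuple
  for (id in c("AD_PHF", "PART", "CTE_I", "CTE_II")) {
    expect_equal(tuple_distance(tuples$AD_SF, tuples[[id]]), 0, info = id)
  }
  # PiD differs from those in sigma_lk(R3, C) (one core entry + its R1 tuple)
  core <- function(x) structure(x[1:6], class = "sign_tuple")
  expect_equal(tuple_distance(core(tuples$AD_SF), core(tuples$PiD)), 1)
  expect_equal(unclass(tuples$PiD)[["(R3,C)"]], "+")
  # PSP differs from GGT by one entry
  expect_equal(tuple_distance(tuples$PSP, tuples$GGT_I), 1)
  # CBD and AGD differ by at most one entry from each other
  expect_lte(tuple_distance(tuples$CBD_I, tuples$AGD_I), 1)
  # ... and by at least 2 entries from PSP and GGT
  # (against GPT type Ia the tabulated values give a distance of 1, so the
  # three-layered folds are only asserted to be distinguishable)
  for (a in c("CBD_I", "CBD_II", "AGD_I", "AGD_II")) {
    for (b in c("PSP", "GGT_I", "GGT_II", "GGT_III", "GPT_Ib", "GPT_II")) {
      expect_gte(tuple_distance(tuples[[a]], tuples[[b]]), 2)
    }
    expect_gte(tuple_distance(tuples[[a]], tuples$GPT_Ia), 1)
  }
  # PSP differs from every GPT type by at least one entry; GGT does too
  # except against GPT type Ib, whose tabulated tuple coincides with GGT's
  for (b in c("GPT_Ia", "GPT_Ib", "GPT_II")) {
    expect_gte(tuple_distance(tuples$PSP, tuples[[b]]), 1)
  }
  for (a in c("GGT_I", "GGT_II", "GGT_III")) {
    for (b in c("GPT_Ia", "GPT_II")) {
      expect_gte(tuple_distance(tuples[[a]], tuples[[b]]), 1)
    }
  }
  # sigma_lk(R4, C) separates the two AGD types
  expect_equal(tuple_distance(tuples$AGD_I, tuples$AGD_II), 1)
  expect_true(unclass(tuples$AGD_I)[["(R4,C)"]] !=
              unclass(tuples$AGD_II)[["(R4,C)"]])
})

test_that("linking matrix entries equal direct fragment linking", {
  set.seed(77)
  v <- matrix(stats::rnorm(36), 12, 3) * 3
  f <- filament_model(polygonal_curve(v), residue_numbers = 101:112)
  m <- linking_matrix(f)
  for (ij in list(c(3, 7), c(4, 10), c(5, 8))) {
    i <- ij[1]; j <- ij[2]
    expect_equal(m[i, j],
                 gauss_linking(subcurve(f, 101, 100 + i - 1),
                               subcurve(f, 100 + i, 100 + j)),
                 tolerance = 1e-12)
    expect_equal(m[j, i],
                 gauss_linking(subcurve(f, 100 + i, 100 + j),
                               subcurve(f, 100 + j + 1, 112)),
                 tolerance = 1e-12)
  }
  # boundary NDs: empty/single-vertex defining fragments
  expect_true(is.na(m[1, 5]))   # preceding part empty
  expect_true(is.na(m[2, 5]))   # preceding part single vertex
  expect_true(is.na(m[12, 4]))  # following part empty
  expect_true(all(is.na(diag(m))))
})

test_that("linking is bilinear over concatenated fragments", {
  c1 <- random_curve(10, seed = 88)
  f <- filament_model(random_curve(20, seed = 89), residue_numbers = 1:20)
  whole <- gauss_linking(c1, subcurve(f, 3, 17))
  split_sum <- gauss_linking(c1, subcurve(f, 3, 9)) +
    gauss_linking(c1, subcurve(f, 9, 17))
  expect_equal(whole, split_sum, tolerance = 1e-12)
})

test_that("fingerprint rendering writes sign-symmetric images", {
  set.seed(5)
  f <- filament_model(random_curve(14, seed = 5), residue_numbers = 1:14)
  m <- linking_matrix(f)
  p1 <- withr::local_tempfile(fileext = ".png")
  render_fingerprint(m, p1)
  expect_true(file.exists(p1) && file.size(p1) > 0)
  neg <- m
  neg[, ] <- -unclass(m)[, ]
  p2 <- withr::local_tempfile(fileext = ".png")
  render_fingerprint(neg, p2)
  expect_true(file.exists(p2) && file.size(p2) > 0)
})

test_that("knotoid flag separates planar curves from genuine knots", {
  flat <- polygonal_curve(cbind(seq_len(15), sin(seq_len(15)), 0))
  kf <- knotoid_flag(flat, n_projections = 400, seed = 2)
  expect_false(kf$flag)
  expect_equal(kf$fraction, 0)
  k52 <- make_knot("5_2")
  kf2 <- knotoid_flag(k52, n_projections = 400, seed = 3)
  expect_true(kf2$flag)
  expect_equal(kf2$fraction, 1)  # every generic projection has value 2
  expect_equal(nrow(kf2$example_directions), 5L)
})
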