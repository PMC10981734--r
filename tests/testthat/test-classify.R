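test_that("a planar filament in an untwisted stack has all-zero features", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_synthetic_fibril(path, n_rungs = 2, twist_deg = 0)
  asm <- read_assembly(path)
  sm <- summarize_filament(asm$filaments[[1]], assembly = asm,
                           filament_index = 1, n_projections = 300, seed = 4)
  expect_equal(sm$Wr, 0, tolerance = 1e-10)
  expect_equal(sm$Lk_s, 0, tolerance = 1e-6)
  expect_equal(sm$v2, 0, tolerance = 1e-12)
  expect_equal(sm$N, 73L)
})

test_that("features are invariant under uniform scaling of coordinates", {
  f <- tau_numbered_helix()
  f2 <- filament_model(polygonal_curve(2 * f$backbone$vertices),
                       residue_numbers = f$residue_numbers)
  a <- summarize_filament(f, n_projections = 500, seed = 6)
  b <- summarize_filament(f2, n_projections = 500, seed = 6)
  expect_equal(a$Wr, b$Wr, tolerance = 1e-10)
  expect_equal(a$v2, b$v2, tolerance = 1e-12)
})

test_that("k-means recovers well-separated synthetic blobs", {
  set.seed(10)
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  truth <- rep(1:3, each = 8)
  x <- centers[truth, ] + matrix(stats::rnorm(72, sd = 0.3), 24, 3)
  s <- tibble::tibble(id = sprintf("f%02d", 1:24),
                      Wr_per_N = x[, 1], Lk_s_per_N = x[, 2], abs_v2 = x[, 3])
  cl <- cluster_summaries(s, k = 3, seed = 1, standardize = FALSE)
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(truth, cl$assignments))), 3L)
  expect_gt(cl$silhouette, 0.8)
})

test_that("k equal to n gives singleton clusters and k > n errors", {
  s <- tau_global_metrics()
  cl <- cluster_summaries(s, k = nrow(s), seed = 1)
  expect_equal(sort(unique(cl$assignments)), seq_len(nrow(s)))
  expect_error(cluster_summaries(s, k = nrow(s) + 1), "must not exceed")
})

test_that("published features cluster AD/PART/CTE together at k = 5", {
  s <- tau_global_metrics()
  cl <- cluster_summaries(s, k = 5, seed = 1)
  grp <- cl$assignments[c("AD_SF", "AD_PHF", "PART", "CTE_I", "CTE_II")]
  expect_equal(length(unique(grp)), 1L)
  members <- names(cl$assignments)[cl$assignments == grp[[1]]]
  expect_setequal(members, c("AD_SF", "AD_PHF", "PART", "CTE_I", "CTE_II"))
})

test_that("the k = 5 partition is stable across seeds (majority vote)", {
  s <- tau_global_metrics()
  hits <- vapply(1:100, function(seed) {
    cl <- cluster_summaries(s, k = 5, seed = seed)
    grp <- cl$assignments[c("AD_SF", "AD_PHF", "PART", "CTE_I", "CTE_II")]
    length(unique(grp)) == 1L &&
      sum(cl$assignments == grp[[1]]) == 5L
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("clustering is deterministic for a fixed seed and label-stable", {
  s <- tau_global_metrics()
  a <- cluster_summaries(s, k = 5, seed = 42)
  b <- cluster_summaries(s, k = 5, seed = 42)
  expect_identical(a$assignments, b$assignments)
  # shuffled row order: identical partition up to label permutation
  set.seed(3)
  s2 <- s[sample(nrow(s)), ]
  c2 <- cluster_summaries(s2, k = 5, seed = 42)
  canon <- function(cl) {
    sort(vapply(split(names(cl$assignments), cl$assignments),
                function(g) paste(sort(g), collapse = "|"), character(1)),
         method = "radix")
  }
  expect_identical(unname(canon(a)), unname(canon(c2)))
})

test_that("handedness follows the sign of the writhe", {
  expect_equal(handedness(-3.65e-3 * 73), "left")
  expect_equal(handedness(2.79e-3 * 110), "right")
  expect_equal(handedness(0), "ND")
  s <- tau_global_metrics()
  h <- handedness(stats::setNames(s$Wr_per_N, s$id))
  expect_true(all(h[c("AD_SF", "AD_PHF", "PART", "CTE_I", "CTE_II", "PiD")] ==
                  "left"))
  expect_true(all(h[c("CBD_II", "AGD_I", "AGD_II", "PSP",
                      "GGT_I", "GGT_II", "GGT_III")] == "right"))
})

test_that("classification report is hierarchical and order-invariant", {
  s <- tau_global_metrics()
  names(s)[names(s) == "Wr_per_N"] <- "Wr_per_N"  # features as printed
  tuples <- lapply(stats::setNames(s$id, s$id), function(id) {
    sign_tuple(tautopo:::published_repeat_table(id))
  })
  rep1 <- classification_report(s, tuples)
  # level 1: split by handedness
  expect_setequal(names(rep1$by_hand), c("left", "right"))
  # PiD sits in its own leaf within the left-handed group
  left_leaves <- rep1$by_hand$left
  pid_leaf <- Filter(function(x) "PiD" %in% x, left_leaves)[[1]]
  expect_equal(pid_leaf, "PiD")
  ad_leaf <- Filter(function(x) "AD_SF" %in% x, left_leaves)[[1]]
  expect_setequal(ad_leaf, c("AD_SF", "AD_PHF", "PART", "CTE_I", "CTE_II"))
  # order invariance
  set.seed(8)
  s2 <- s[sample(nrow(s)), ]
  rep2 <- classification_report(s2, tuples)
  expect_identical(rep1$by_hand, rep2$by_hand)
  expect_identical(rep1$tuple_distances, rep2$tuple_distances)
  # all-identical filaments collapse to a single leaf
  s3 <- s[1:3, ]
  s3$Wr_per_N <- -1
  t3 <- tuples[s3$id]
  for (id in s3$id) t3[[id]] <- tuples$AD_SF
  rep3 <- classification_report(s3, t3)
  expect_equal(length(rep3$by_hand), 1L)
  expect_equal(length(rep3$by_hand$left), 1L)
})

test_that("report export writes JSON and Markdown", {
  s <- tau_global_metrics()[1:6, ]
  tuples <- lapply(stats::setNames(s$id, s$id), function(id) {
    sign_tuple(tautopo:::published_repeat_table(id))
  })
  rep1 <- classification_report(s, tuples,
                                clusters = cluster_summaries(
                                  tau_global_metrics(), 5, seed = 1))
  jp <- withr::local_tempfile(fileext = ".json")
  mp <- withr::local_tempfile(fileext = ".md")
  write_report(rep1, json_path = jp, md_path = mp)
  expect_true(jsonlite::validate(paste(readLines(jp), collapse = "")))
  expect_true(any(grepl("left-handed", readLines(mp))))
})
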