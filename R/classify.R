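#' Global topological summary of one filament
#'
#' Computes the feature set used for filament classification: the writhe
#' and its per-residue normalization, the mean linking number with stacked
#' neighbor filaments (when an assembly is supplied), and the
#' projection-sampled second Vassiliev measure with its Monte-Carlo
#' standard error. Rigid motions and uniform scaling of the coordinates
#' leave every feature unchanged.
#'
#' @param f A `filament_model`.
#' @param assembly Optional `stacked_assembly` containing `f`.
#' @param filament_index Index of `f` within the assembly (default: matched
#'   by identical backbone).
#' @param n_projections,seed Passed to [vassiliev2()].
#' @return One-row tibble of class `topology_summary` with columns `id`,
#'   `N`, `Wr`, `Wr_per_N`, `Lk_s`, `Lk_s_per_N`, `v2`, `abs_v2`, `v2_se`,
#'   `seed`, `n_projections`.
#' @export
summarize_filament <- function(f, assembly = NULL, filament_index = NULL,
                               n_projections = 1e4, seed = NULL) {
  stopifnot(inherits(f, "filament_model"))
  n <- n_vertices(f$backbone)
  wr <- writhe(f$backbone)
  lk_s <- NA_real_; lk_s_n <- NA_real_
  if (!is.null(assembly)) {
    if (is.null(filament_index)) {
      filament_index <- which(vapply(assembly$filaments, function(g) {
        isTRUE(all.equal(g$backbone$vertices, f$backbone$vertices))
      }, logical(1)))[1]
      if (is.na(filament_index)) stop("`f` not found in `assembly`")
    }
    sl <- stacked_linking(assembly, filament_index)
    lk_s <- sl$Lk_s; lk_s_n <- sl$Lk_s_per_N
  }
  vr <- vassiliev2(f$backbone, n_projections = n_projections, seed = seed)
  out <- tibble::tibble(
    id = if (nzchar(f$accession)) f$accession else f$backbone$label,
    N = n, Wr = wr, Wr_per_N = wr / n,
    Lk_s = lk_s, Lk_s_per_N = lk_s_n,
    v2 = vr$estimate, abs_v2 = abs(vr$estimate), v2_se = vr$se,
    seed = vr$seed, n_projections = vr$n_projections)
  class(out) <- c("topology_summary", class(out))
  out
}

#' Published global topological metrics of the tau filament dataset
#'
#' The per-filament global features of the 17 reference tau filament
#' structures, as printed (all values are multiples of 1e-3; the second
#' Vassiliev measure is not length-normalized): normalized writhe `Wr_per_N`,
#' normalized stacked-filament linking `Lk_s_per_N`, and `abs_v2`. Used as
#' typed-in feature vectors for clustering demonstrations.
#'
#' @return Tibble with columns `id`, `disease`, `fold_class`, `accession`,
#'   `Wr_per_N`, `Lk_s_per_N`, `abs_v2`.
#' @export
tau_global_metrics <- function() {
  tibble::tribble(
    ~id,        ~disease, ~fold_class, ~accession, ~Wr_per_N, ~Lk_s_per_N, ~abs_v2,
    "AD_SF",    "AD",     "3R+4R",     "5o3t",     -3.65,      0.990,       0.640,
    "AD_PHF",   "AD",     "3R+4R",     "5o3l",     -3.59,      1.15,        0.585,
    "PART",     "PART",   "3R+4R",     "7nrq",     -0.350,     1.41,        0.765,
    "CTE_I",    "CTE",    "3R+4R",     "6nwp",     -0.269,     1.06,        0.255,
    "CTE_II",   "CTE",    "3R+4R",     "6nwq",     -0.104,     0.904,       0.360,
    "PiD",      "PiD",    "3R",        "6gx5",     -1.02,      0.145,       0.130,
    "CBD_I",    "CBD",    "4R",        "6tjo",     -0.154,     0.627,       1.05,
    "CBD_II",   "CBD",    "4R",        "6tjx",      0.603,     0.518,       1.06,
    "AGD_I",    "AGD",    "4R",        "7p6d",      1.26,      0.649,       0.620,
    "AGD_II",   "AGD",    "4R",        "7p6e",      0.325,     0.303,       1.43,
    "PSP",      "PSP",    "4R",        "7p65",      2.79,      1.26,        2.69,
    "GGT_I",    "GGT",    "4R",        "7p66",      3.68,      0.642,       0.105,
    "GGT_II",   "GGT",    "4R",        "7p67",      4.28,      0.590,       0.300,
    "GGT_III",  "GGT",    "4R",        "7p68",      3.68,      0.138,       0.205,
    "GPT_Ia",   "GPT",    "4R",        "7p6a",      1.71,      0.001,       2.39,
    "GPT_Ib",   "GPT",    "4R",        "7p6b",      0.986,     0.688,       0.150,
    "GPT_II",   "GPT",    "4R",        "7p6c",      1.15,      0.174,       2.54)
}

#' Published repeat-pair linking numbers of the tau filament dataset
#'
#' The pairwise repeat/C-terminal linking numbers of the 17 reference
#' filaments as printed (multiples of 1e-2; `NA` = Not Defined). One column
#' per filament id matching [tau_global_metrics()].
#'
#' @return Tibble with columns `a`, `b` (region pair) and one numeric
#'   column per filament.
#' @export
tau_repeat_linking <- function() {
  pr <- repeat_pairs()
  vals <- rbind(
    # R1R3     R1R4    R1C     R2R3    R2R4    R2C     R3R4     R3C      R4C
    c(NA,      NA,     NA,     NA,     NA,     NA,     -2.01,   -1.87,   -2.19),   # AD_SF
    c(NA,      NA,     NA,     NA,     NA,     NA,     -2.85,   -1.89,   -1.59),   # AD_PHF
    c(NA,      NA,     NA,     NA,     NA,     NA,     -1.76,   -0.841,  -1.80),   # PART
    c(NA,      NA,     NA,     NA,     NA,     NA,     -1.88,   -1.61,   -1.69),   # CTE_I
    c(NA,      NA,     NA,     NA,     NA,     NA,     -2.80,   -0.590,  -1.82),   # CTE_II
    c(-0.446,  4.55,   -1.21,  NA,     NA,     NA,     -0.0567,  0.0720, -0.350),  # PiD
    c(NA,      NA,     NA,     3.85,   3.53,   1.39,   -0.807,  -0.384,   0.352),  # CBD_I
    c(NA,      NA,     NA,     4.08,   3.32,   1.72,   -0.991,  -0.465,   0.725),  # CBD_II
    c(NA,      NA,     NA,     3.64,   3.16,   4.18,   -0.620,  -0.595,   0.0262), # AGD_I
    c(NA,      NA,     NA,     3.45,   3.68,   0.122,  -0.496,  -0.545,  -0.0313), # AGD_II
    c(NA,      NA,     NA,     0.378,  -4.55,  2.06,   14.0,     0.413,   5.24),   # PSP
    c(NA,      NA,     NA,     9.88,   -4.75,  0.861,  4.80,    -0.958,   0.300),  # GGT_I
    c(NA,      NA,     NA,     9.90,   -5.28,  0.962,  5.36,    -1.06,    0.213),  # GGT_II
    c(NA,      NA,     NA,     8.98,   -4.57,  0.843,  5.39,    -1.07,    0.255),  # GGT_III
    c(NA,      NA,     NA,     -1.90,  1.18,   1.24,   -1.32,   -0.278,   0.638),  # GPT_Ia
    c(NA,      NA,     NA,     2.34,   -9.54,  2.41,   2.88,    -1.37,    0.608),  # GPT_Ib
    c(NA,      NA,     NA,     -3.43,  -6.28,  2.02,   3.19,    -1.42,    0.685))  # GPT_II
  ids <- tau_global_metrics()$id
  out <- tibble::as_tibble(as.data.frame(t(vals)))
  names(out) <- ids
  tibble::as_tibble(cbind(data.frame(a = pr[, 1], b = pr[, 2],
                                     stringsAsFactors = FALSE), out))
}

# Rebuild a repeat_link_table for one filament column of tau_repeat_linking().
published_repeat_table <- function(id) {
  tab <- tau_repeat_linking()
  if (!id %in% names(tab)) stop("unknown filament id: ", id)
  structure(data.frame(a = tab$a, b = tab$b, lk = tab[[id]],
                       stringsAsFactors = FALSE),
            class = c("repeat_link_table", "data.frame"))
}

#' K-means clustering of global topological features
#'
#' Clusters filaments on the 3-feature vectors (Wr/N, Lk_s/N, |v2|). By
#' default the features are z-scored before clustering (they live on
#' different effective scales even though all are multiples of 1e-3);
#' `standardize = FALSE` clusters the raw values. The silhouette width is
#' reported as the clustering quality score.
#'
#' @param summaries Data frame with columns `id`, `Wr_per_N`, `Lk_s_per_N`,
#'   `abs_v2` (e.g. rows of [summarize_filament()] output, or
#'   [tau_global_metrics()]).
#' @param k Number of clusters (`1 <= k <= nrow`).
#' @param seed Integer seed (K-means with a fixed seed is deterministic).
#' @param nstart Random restarts.
#' @param standardize z-score the features first.
#' @return List of class `cluster_result`: `k`, `assignments` (named
#'   integer vector), `silhouette` (mean silhouette width; `NA` for k = 1
#'   or k = n), `withinss`, `seed`, `standardize`.
#' @export
cluster_summaries <- function(summaries, k, seed = 1, nstart = 10,
                              standardize = TRUE) {
  feats <- c("Wr_per_N", "Lk_s_per_N", "abs_v2")
  stopifnot(all(feats %in% names(summaries)))
  x <- as.matrix(summaries[, feats])
  if (anyNA(x)) stop("feature matrix contains NA")
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of filaments")
  rownames(x) <- summaries$id
  if (standardize) x <- scale(x)
  set.seed(as.integer(seed))
  if (k == n) {
    assignments <- stats::setNames(seq_len(n), rownames(x))
    withinss <- rep(0, n)
  } else {
    km <- stats::kmeans(x, centers = k, nstart = nstart)
    assignments <- stats::setNames(km$cluster, rownames(x))
    withinss <- km$withinss
  }
  sil <- NA_real_
  if (k > 1L && k < n) {
    sw <- cluster::silhouette(assignments, stats::dist(x))
    sil <- mean(sw[, "sil_width"])
  }
  structure(list(k = k, assignments = assignments, silhouette = sil,
                 withinss = withinss, seed = seed,
                 standardize = standardize),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, mean silhouette width = %s\n",
              x$k, format(x$silhouette, digits = 3)))
  for (g in sort(unique(x$assignments))) {
    cat(sprintf("  [%d] %s\n", g,
                paste(names(x$assignments)[x$assignments == g],
                      collapse = ", ")))
  }
  invisible(x)
}

#' Handedness of a filament conformation
#'
#' Negative writhe indicates a left-handed global conformation, positive
#' writhe a right-handed one.
#'
#' @param wr A writhe value, or a `topology_summary` row (its `Wr` is used).
#' @return `"left"`, `"right"`, or `"ND"` for exactly zero.
#' @export
handedness <- function(wr) {
  if (is.data.frame(wr)) wr <- wr$Wr
  vapply(wr, function(w) {
    if (is.na(w)) "ND" else if (w < 0) "left" else if (w > 0) "right" else "ND"
  }, character(1))
}

#' Hierarchical topological classification report
#'
#' Assembles the classification hierarchy: level 1 splits filaments by the
#' sign of their writhe (handedness); levels 2-3 subdivide each handedness
#' group by identical repeat-linking sign tuples. Cluster labels and the
#' pairwise tuple-distance matrix are included. The report is deterministic
#' and invariant under input ordering.
#'
#' @param summaries Data frame with columns `id` and `Wr_per_N` (or `Wr`).
#' @param tuples Named list of `sign_tuple` objects, one per filament id.
#' @param clusters Optional `cluster_result` whose assignments are attached.
#' @return List of class `classification_report` with elements `by_hand`
#'   (leaf groups per handedness, each leaf = ids sharing a sign tuple),
#'   `tuple_distances` (matrix), `clusters`, `provenance`.
#' @export
classification_report <- function(summaries, tuples, clusters = NULL) {
  ids <- sort(summaries$id)
  wr <- summaries[[if ("Wr" %in% names(summaries)) "Wr" else "Wr_per_N"]]
  names(wr) <- summaries$id
  stopifnot(all(ids %in% names(tuples)))
  hand <- handedness(wr[ids])
  names(hand) <- ids
  key <- vapply(ids, function(id) paste(unclass(tuples[[id]]), collapse = ","),
                character(1))
  by_hand <- lapply(split(ids, hand[ids]), function(group) {
    unname(lapply(split(group, key[group]), sort))
  })
  m <- length(ids)
  dmat <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      dmat[i, j] <- tuple_distance(tuples[[ids[i]]], tuples[[ids[j]]])
    }
  }
  structure(list(by_hand = by_hand, tuple_distances = dmat,
                 clusters = if (!is.null(clusters)) clusters$assignments[ids],
                 provenance = list(
                   n_filaments = m,
                   cluster_quality = if (!is.null(clusters)) clusters$silhouette,
                   note = paste("cluster quality is the mean silhouette width;",
                                "no claim is made about any other accuracy metric"))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  for (h in names(x$by_hand)) {
    cat(h, "-handed:\n", sep = "")
    for (leaf in x$by_hand[[h]]) {
      cat("  - ", paste(leaf, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a classification report as JSON and Markdown
#'
#' @param report A `classification_report`.
#' @param json_path,md_path Output paths (either may be `NULL`).
#' @return Invisibly, the list of written paths.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "classification_report"))
  written <- list()
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, digits = NA,
                         auto_unbox = TRUE, matrix = "rowmajor")
    written$json <- json_path
  }
  if (!is.null(md_path)) {
    con <- file(md_path, "w")
    on.exit(close(con))
    writeLines("# Topological classification", con)
    for (h in names(report$by_hand)) {
      writeLines(sprintf("\n## %s-handed", h), con)
      for (leaf in report$by_hand[[h]]) {
        writeLines(paste0("- ", paste(leaf, collapse = ", ")), con)
      }
    }
    written$md <- md_path
  }
  invisible(written)
}
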