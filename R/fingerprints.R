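# Repeat pairs reported in the repeat-linking table: all pairs among
# R1..R4 and C except the sequence-adjacent (R1, R2).
repeat_pairs <- function() {
  rbind(c("R1", "R3"), c("R1", "R4"), c("R1", "C"),
        c("R2", "R3"), c("R2", "R4"), c("R2", "C"),
        c("R3", "R4"), c("R3", "C"), c("R4", "C"))
}

#' Linking numbers between repeat regions of a filament
#'
#' The Gauss linking number between the CA sub-curves of each repeat pair
#' (R1-R4 and the C-terminal region; the adjacent pair R1/R2 is not
#' tabulated). Pairs involving a repeat that is absent from the ordered core
#' (fewer than two resolved residues) are Not Defined (`NA`).
#'
#' @param f An annotated `filament_model`.
#' @return A data frame of class `repeat_link_table` with columns `a`, `b`,
#'   `lk`.
#' @export
repeat_linking <- function(f) {
  stopifnot(inherits(f, "filament_model"))
  pr <- repeat_pairs()
  curves <- list()
  for (rg in unique(c(pr))) {
    res <- region_residues(f, rg)
    curves[[rg]] <- if (length(res) >= 2L) subcurve(f, min(res), max(res))
  }
  lk <- vapply(seq_len(nrow(pr)), function(k) {
    ca <- curves[[pr[k, 1]]]; cb <- curves[[pr[k, 2]]]
    if (is.null(ca) || is.null(cb)) return(NA_real_)
    gauss_linking(ca, cb)
  }, numeric(1))
  structure(data.frame(a = pr[, 1], b = pr[, 2], lk = lk,
                       stringsAsFactors = FALSE),
            class = c("repeat_link_table", "data.frame"))
}

#' Sign tuple of a repeat linking table
#'
#' Encodes the signs of the six pairwise linking numbers among R2, R3, R4
#' and C (the primary 6-tuple), plus the three R1 entries as an extra tuple
#' when R1 is part of the ordered core. Exact zeros and undefined pairs map
#' to `"ND"`.
#'
#' @param t A `repeat_link_table` from [repeat_linking()].
#' @return Named character vector of class `sign_tuple` with values `"+"`,
#'   `"-"`, `"ND"`; the six core entries first, the R1 entries appended only
#'   when at least one is defined.
#' @export
sign_tuple <- function(t) {
  stopifnot(inherits(t, "repeat_link_table"))
  lab <- paste0("(", t$a, ",", t$b, ")")
  s <- ifelse(is.na(t$lk) | t$lk == 0, "ND", ifelse(t$lk > 0, "+", "-"))
  names(s) <- lab
  core <- c("(R2,R3)", "(R2,R4)", "(R2,C)", "(R3,R4)", "(R3,C)", "(R4,C)")
  extra <- c("(R1,R3)", "(R1,R4)", "(R1,C)")
  out <- s[core]
  if (any(s[extra] != "ND", na.rm = TRUE)) out <- c(out, s[extra])
  structure(out, class = "sign_tuple")
}

#' @export
print.sign_tuple <- function(x, ...) {
  cat("(", paste(unclass(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Hamming distance between sign tuples
#'
#' Counts differing entries over the union of tuple positions (shorter
#' tuples are ND-padded): an `ND`-vs-sign mismatch counts as a difference,
#' `ND`-vs-`ND` as equal.
#'
#' @param a,b `sign_tuple` objects.
#' @return Integer count of differing entries.
#' @export
tuple_distance <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), unclass(a)[keys], "ND")
  bv <- ifelse(keys %in% names(b), unclass(b)[keys], "ND")
  sum(av != bv)
}

# Block sum of the per-edge-pair Gauss matrix via 2-D prefix sums:
# rows a..b against columns c..d.
block_sum <- function(P, a, b, c, d) {
  if (a > b || c > d) return(0)
  P[b + 1L, d + 1L] - P[a, d + 1L] - P[b + 1L, c] + P[a, c]
}

#' Residue-resolved linking matrix of a filament
#'
#' For a filament with first resolved residue K and last N, the entry above
#' the diagonal `a[i, j]` (i < j) is the linking number between the fragment
#' `p[i, j]` (residues i..j inclusive) and the preceding part `p[K, i-1]`;
#' the entry below the diagonal `a[j, i]` is the linking number between
#' `p[i, j]` and the following part `p[j+1, N]`. Entries whose defining
#' fragment is empty or a single vertex are Not Defined (`NA`); the diagonal
#' is unused. Fragment-vs-fragment linking numbers are computed exactly from
#' the per-segment-pair Gauss contributions, so the matrix is bilinear under
#' fragment concatenation by construction.
#'
#' @param f A `filament_model` with at least 4 residues.
#' @param stride Compute entries only every `stride` residues (speed knob;
#'   1 = full residue resolution).
#' @return A square matrix of class `linking_matrix`, dimnames = residue
#'   numbers.
#' @export
linking_matrix <- function(f, stride = 1L) {
  stopifnot(inherits(f, "filament_model"))
  rn <- f$residue_numbers
  n <- length(rn)
  if (n < 4L) stop("linking matrix needs at least 4 residues")
  g <- segment_gauss_matrix(f)
  e <- n - 1L
  P <- matrix(0, e + 1L, e + 1L)
  P[-1L, -1L] <- apply(apply(g, 2L, cumsum), 1L, cumsum)
  P[-1L, -1L] <- t(P[-1L, -1L, drop = FALSE])
  idx <- seq(1L, n, by = as.integer(stride))
  m <- matrix(NA_real_, length(idx), length(idx),
              dimnames = list(rn[idx], rn[idx]))
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      if (i >= j) next
      # above diagonal: fragment (i..j) vs preceding part (1..i-1)
      if (i >= 3L) {                       # preceding part has >= 2 vertices
        m[ii, jj] <- block_sum(P, 1L, i - 2L, i, j - 1L)
      }
      # below diagonal: fragment (i..j) vs following part (j+1..n)
      if (j <= n - 2L) {
        m[jj, ii] <- block_sum(P, i, j - 1L, j + 1L, e)
      }
    }
  }
  structure(m, class = c("linking_matrix", "matrix"),
            accession = f$accession, chain_id = f$chain_id, stride = stride)
}

#' Render a linking matrix as a fingerprint image
#'
#' Diverging colormap: sign maps to hue (blue negative, orange positive),
#' magnitude to intensity; ND cells are neutral grey. Axes are labeled with
#' residue numbers.
#'
#' @param m A `linking_matrix`.
#' @param out_path Output image path (`.png`, `.svg`, `.pdf` — any device
#'   `ggplot2::ggsave` understands).
#' @param title Optional plot title.
#' @return `out_path`, invisibly.
#' @export
render_fingerprint <- function(m, out_path, title = NULL) {
  stopifnot(inherits(m, "linking_matrix"))
  rn <- as.integer(rownames(m))
  df <- expand.grid(i = rn, j = rn)
  df$lk <- as.vector(m[, ])  # column-major: i runs fastest, matching expand.grid
  lim <- max(abs(df$lk), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = j, y = i, fill = lk)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#e08214", midpoint = 0,
                                  limits = c(-lim, lim),
                                  na.value = "grey85", name = "Lk") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue", title = title) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(out_path, p, width = 6, height = 5.2, dpi = 150)
  invisible(out_path)
}

#' Flag knotoid character of an open filament
#'
#' A filament is flagged as realizing a non-trivial knotoid when the
#' fraction of sampled projection directions whose diagram has a per-diagram
#' second Vassiliev value of at least 0.5 exceeds `threshold`. Example
#' qualifying directions are returned for inspection.
#'
#' @param f A `filament_model` or `polygonal_curve`.
#' @param threshold Qualifying-projection fraction above which the flag is
#'   `TRUE`.
#' @param n_projections,seed Passed to [vassiliev2()] unless `v2` is given.
#' @param v2 Optional precomputed [vassiliev2()] result with
#'   `keep_values = TRUE`.
#' @return List with `flag`, `fraction`, `n_qualifying`,
#'   `example_directions` (up to 5 rows), `threshold`.
#' @export
knotoid_flag <- function(f, threshold = 0.01, n_projections = 1e4,
                         seed = NULL, v2 = NULL) {
  curve <- if (inherits(f, "filament_model")) f$backbone else f
  if (is.null(v2)) {
    v2 <- vassiliev2(curve, n_projections = n_projections, seed = seed,
                     keep_values = TRUE)
  }
  if (is.null(v2$values)) {
    stop("`v2` must be computed with keep_values = TRUE")
  }
  qual <- which(abs(v2$values) >= 0.5)
  frac <- length(qual) / length(v2$values)
  list(flag = frac > threshold, fraction = frac,
       n_qualifying = length(qual),
       example_directions = v2$directions[utils::head(qual, 5L), , drop = FALSE],
       threshold = threshold)
}

#' Export repeat-linking tables and linking matrices as CSV
#'
#' @param x A `repeat_link_table` or `linking_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_topology_csv <- function(x, path) {
  if (inherits(x, "linking_matrix")) {
    utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
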