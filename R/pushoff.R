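#' Linking number of a backbone with its side-chain push-off
#'
#' The backbone and the push-off bound an open ribbon; their Gauss linking
#' number counts the net turns of the side chains about the backbone. With
#' the ribbon relation Tw = Lk - Wr and the small writhe of flat filament
#' folds, this linking number approximates the ribbon twist.
#'
#' @param backbone,push `polygonal_curve` objects with equal vertex counts
#'   and disjoint vertices.
#' @return The linking number (double).
#' @export
ribbon_linking <- function(backbone, push) {
  check_topology_curve(backbone, 2L, "backbone")
  check_topology_curve(push, 2L, "push")
  if (n_vertices(backbone) != n_vertices(push)) {
    stop("backbone and push-off must have equal vertex counts")
  }
  gauss_linking(backbone, push)
}

#' Ribbon linking restricted to a repeat region
#'
#' Both curves are truncated to exactly the residues inside the region
#' interval (no flanking vertices) before the linking number is computed.
#' A region absent from the ordered core reports 0.
#'
#' @param f A `filament_model` carrying a push-off.
#' @param region Region name (`"R1"`..`"R4"`, `"C"`).
#' @return The region's backbone/push-off linking number; 0 for an
#'   unresolved region.
#' @export
repeat_ribbon_linking <- function(f, region) {
  stopifnot(inherits(f, "filament_model"))
  if (is.null(f$pushoff)) stop("filament has no push-off; see build_pushoff()")
  res <- region_residues(f, region)
  if (length(res) < 2L) return(0)
  idx <- which(f$residue_numbers %in% res)
  bb <- polygonal_curve(f$backbone$vertices[idx, , drop = FALSE])
  po <- polygonal_curve(f$pushoff$vertices[idx, , drop = FALSE])
  ribbon_linking(bb, po)
}

#' Ribbon twist from linking number and writhe
#'
#' The ribbon relation Tw = Lk - Wr.
#'
#' @param lk Linking number of the ribbon's boundary curves.
#' @param wr Writhe of the axis curve.
#' @return `lk - wr`.
#' @export
twist <- function(lk, wr) lk - wr

#' Whole-filament and per-region ribbon summary
#'
#' Computes the backbone/push-off linking number of the whole filament and
#' of every repeat region, each with two normalizations (per region length
#' and per filament length), plus the twist Tw = Lk - Wr(backbone).
#'
#' @param f A `filament_model` carrying a push-off.
#' @return A list of class `ribbon_summary`: `Lk`, `Lk_per_N`, `Wr`, `Tw`,
#'   and a data frame `regions` with `lk`, `lk_per_region` (divided by the
#'   region's residue count) and `lk_per_N` (divided by the filament
#'   length).
#' @export
ribbon_summary <- function(f) {
  stopifnot(inherits(f, "filament_model"))
  if (is.null(f$pushoff)) stop("filament has no push-off; see build_pushoff()")
  n <- n_vertices(f$backbone)
  lk <- ribbon_linking(f$backbone, f$pushoff)
  wr <- writhe(f$backbone)
  regions <- c("R1", "R2", "R3", "R4", "C")
  lk_r <- vapply(regions, function(r) repeat_ribbon_linking(f, r), numeric(1))
  len_r <- vapply(regions, function(r) length(region_residues(f, r)), numeric(1))
  reg <- data.frame(region = regions, n_residues = len_r, lk = lk_r,
                    lk_per_region = ifelse(len_r > 0, lk_r / len_r, 0),
                    lk_per_N = lk_r / n, stringsAsFactors = FALSE)
  structure(list(Lk = lk, Lk_per_N = lk / n, Wr = wr, Tw = twist(lk, wr),
                 N = n, regions = reg, accession = f$accession,
                 chain_id = f$chain_id),
            class = "ribbon_summary")
}

#' @export
print.ribbon_summary <- function(x, ...) {
  cat(sprintf("<ribbon_summary> %s: Lk = %.4g (Lk/N = %.4g), Wr = %.4g, Tw = %.4g\n",
              x$accession, x$Lk, x$Lk_per_N, x$Wr, x$Tw))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' @rdname write_topology_csv
#' @export
write_ribbon_csv <- function(x, path) {
  stopifnot(inherits(x, "ribbon_summary"))
  whole <- data.frame(region = "filament", n_residues = x$N, lk = x$Lk,
                      lk_per_region = x$Lk_per_N, lk_per_N = x$Lk_per_N)
  utils::write.csv(rbind(whole, x$regions), path, row.names = FALSE)
  invisible(path)
}
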