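#' Polygonal curve in 3-space
#'
#' An ordered chain of 3-D vertices, the basic geometric object of the
#' package. Protein backbones are stored N- to C-terminus; the storage order
#' is the orientation used by all topological measures.
#'
#' @param vertices Numeric matrix with 3 columns (x, y, z in Angstrom), one
#'   row per vertex, or anything coercible to one.
#' @param closed Logical; `TRUE` joins the last vertex back to the first.
#' @param label Free-text label carried through to results.
#'
#' @return An object of class `polygonal_curve` with elements `vertices`,
#'   `closed`, `label`.
#' @examples
#' square <- polygonal_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'                           closed = TRUE)
#' n_vertices(square)
#' @export
polygonal_curve <- function(vertices, closed = FALSE, label = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) {
    stop("`vertices` must have exactly 3 columns (x, y, z)")
  }
  if (nrow(vertices) < 2L) {
    stop("a polygonal curve needs at least 2 vertices")
  }
  if (!all(is.finite(vertices))) {
    stop("all vertex coordinates must be finite")
  }
  steps <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                           vertices[-nrow(vertices), , drop = FALSE])^2))
  if (any(steps == 0)) {
    stop("consecutive vertices must not coincide")
  }
  if (closed &&
      sqrt(sum((vertices[1L, ] - vertices[nrow(vertices), ])^2)) == 0) {
    stop("for a closed curve do not repeat the first vertex at the end")
  }
  structure(list(vertices = unname(vertices), closed = isTRUE(closed),
                 label = as.character(label)),
            class = "polygonal_curve")
}

# Internal: a single-point "curve" as returned by subcurve(f, k, k).
# Invalid as input to any topological measure; carries degenerate = TRUE.
degenerate_curve <- function(vertex, label = "") {
  out <- structure(list(vertices = matrix(as.double(vertex), 1L, 3L),
                        closed = FALSE, label = as.character(label)),
                   class = "polygonal_curve")
  attr(out, "degenerate") <- TRUE
  out
}

#' @rdname polygonal_curve
#' @param x A `polygonal_curve`.
#' @export
n_vertices <- function(x) nrow(x$vertices)

#' @export
print.polygonal_curve <- function(x, ...) {
  kind <- if (x$closed) "closed" else "open"
  cat(sprintf("<polygonal_curve> %s, %d vertices%s\n", kind, n_vertices(x),
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Reverse the orientation of a curve
#'
#' Reversal negates the Gauss linking number of the curve with any fixed
#' partner and negates its writhe.
#'
#' @param x A `polygonal_curve`.
#' @return The same curve traversed in the opposite order.
#' @export
reverse_curve <- function(x) {
  stopifnot(inherits(x, "polygonal_curve"))
  polygonal_curve(x$vertices[rev(seq_len(nrow(x$vertices))), , drop = FALSE],
                  closed = x$closed, label = x$label)
}

#' Mirror-reflect a curve through the xy-plane
#'
#' Reflection flips chirality: linking numbers, writhe and signed crossing
#' data all change sign.
#'
#' @param x A `polygonal_curve`.
#' @return The reflected curve.
#' @export
mirror_curve <- function(x) {
  stopifnot(inherits(x, "polygonal_curve"))
  v <- x$vertices
  v[, 3] <- -v[, 3]
  polygonal_curve(v, closed = x$closed, label = x$label)
}

#' Microtubule-binding repeat boundary table
#'
#' Default residue intervals of the tau repeats used to annotate filament
#' cores: R1 244-274, R2 275-305, R3 306-336, R4 337-368, and the C-terminal
#' region from 369 onwards. Author residue numbering, 1-based, inclusive.
#' Per-filament annotation is the intersection of these intervals with the
#' resolved residues; a repeat absent from the core is Not Defined (ND).
#'
#' @param c_end Last residue of the C-terminal interval (the table is open
#'   ended; any resolved residue past 369 is "C").
#' @return A data frame with columns `name`, `start`, `end`.
#' @examples
#' repeat_range_table()
#' @export
repeat_range_table <- function(c_end = 441L) {
  data.frame(name = c("R1", "R2", "R3", "R4", "C"),
             start = c(244L, 275L, 306L, 337L, 369L),
             end = c(274L, 305L, 336L, 368L, as.integer(c_end)),
             stringsAsFactors = FALSE)
}

#' Filament model: a labeled CA backbone
#'
#' Couples a backbone curve with author residue numbers, repeat annotation
#' and, optionally, a side-chain push-off curve with one vertex per residue.
#'
#' @param backbone A `polygonal_curve` (open, N- to C-terminus).
#' @param residue_numbers Strictly increasing integer vector, one entry per
#'   backbone vertex.
#' @param repeats Repeat boundary table as from [repeat_range_table()].
#' @param pushoff Optional `polygonal_curve`, exactly one vertex per backbone
#'   vertex.
#' @param accession,chain_id Provenance strings.
#' @return An object of class `filament_model`.
#' @export
filament_model <- function(backbone, residue_numbers,
                           repeats = repeat_range_table(),
                           pushoff = NULL, accession = "", chain_id = "") {
  stopifnot(inherits(backbone, "polygonal_curve"))
  residue_numbers <- as.integer(residue_numbers)
  if (length(residue_numbers) != n_vertices(backbone)) {
    stop("`residue_numbers` must have one entry per backbone vertex")
  }
  if (any(diff(residue_numbers) <= 0L)) {
    stop("`residue_numbers` must be strictly increasing")
  }
  if (!is.null(pushoff)) {
    stopifnot(inherits(pushoff, "polygonal_curve"))
    if (n_vertices(pushoff) != n_vertices(backbone)) {
      stop("push-off must have exactly one vertex per backbone vertex")
    }
  }
  repeats <- as.data.frame(repeats)
  stopifnot(all(c("name", "start", "end") %in% names(repeats)))
  if (any(repeats$start > repeats$end)) stop("repeat ranges need start <= end")
  o <- order(repeats$start)
  if (any(repeats$end[o][-nrow(repeats)] >= repeats$start[o][-1L])) {
    stop("repeat ranges must not overlap")
  }
  structure(list(backbone = backbone, residue_numbers = residue_numbers,
                 repeats = repeats, pushoff = pushoff,
                 accession = as.character(accession),
                 chain_id = as.character(chain_id)),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  rn <- x$residue_numbers
  cat(sprintf("<filament_model> %s%s: %d residues (%d-%d)%s\n",
              x$accession,
              if (nzchar(x$chain_id)) paste0("/", x$chain_id) else "",
              length(rn), min(rn), max(rn),
              if (!is.null(x$pushoff)) ", with push-off" else ""))
  invisible(x)
}

#' Extract the sub-curve between two residues
#'
#' Returns the vertex chain of residues `k..l` inclusive, orientation
#' preserved. With `k == l` a single-vertex degenerate curve is returned,
#' flagged via `attr(, "degenerate")`; such a curve is rejected by all
#' topological measures.
#'
#' @param f A `filament_model`.
#' @param k,l First and last residue number (author numbering, inclusive),
#'   `k <= l`. Both must be resolved in `f`.
#' @return A `polygonal_curve` (or degenerate single-vertex curve).
#' @export
subcurve <- function(f, k, l) {
  stopifnot(inherits(f, "filament_model"))
  k <- as.integer(k); l <- as.integer(l)
  if (k > l) stop("`k` must be <= `l`")
  rn <- f$residue_numbers
  if (k < min(rn) || l > max(rn)) {
    stop(sprintf("residue range %d-%d outside resolved range %d-%d",
                 k, l, min(rn), max(rn)))
  }
  idx <- which(rn >= k & rn <= l)
  if (length(idx) == 0L) {
    stop(sprintf("no resolved residues in %d-%d", k, l))
  }
  lab <- sprintf("%s[%d-%d]", f$accession, k, l)
  if (length(idx) == 1L) {
    return(degenerate_curve(f$backbone$vertices[idx, ], label = lab))
  }
  polygonal_curve(f$backbone$vertices[idx, , drop = FALSE],
                  closed = FALSE, label = lab)
}

#' Annotate resolved residues with repeat membership
#'
#' Every resolved residue is assigned to exactly one region: one of the
#' repeats, the C-terminal region, or `"pre-R1"` for residues before the
#' first repeat boundary.
#'
#' @param f A `filament_model`.
#' @return Data frame with columns `residue` and `region`.
#' @export
annotate_repeats <- function(f) {
  stopifnot(inherits(f, "filament_model"))
  rn <- f$residue_numbers
  region <- rep("pre-R1", length(rn))
  for (i in seq_len(nrow(f$repeats))) {
    hit <- rn >= f$repeats$start[i] & rn <= f$repeats$end[i]
    region[hit] <- f$repeats$name[i]
  }
  region[rn > max(f$repeats$end)] <- f$repeats$name[which.max(f$repeats$end)]
  data.frame(residue = rn, region = region, stringsAsFactors = FALSE)
}

#' Resolved interval of a repeat region within a filament
#'
#' @param f A `filament_model`.
#' @param region Region name (`"R1"`..`"R4"`, `"C"`).
#' @return Integer vector of resolved residue numbers in the region (may be
#'   empty when the region is absent from the ordered core).
#' @export
region_residues <- function(f, region) {
  ann <- annotate_repeats(f)
  ann$residue[ann$region == region]
}

#' Serialize / restore a filament model as JSON
#'
#' A plain JSON record used for caching extracted backbones.
#'
#' @param f A `filament_model`.
#' @param path File path.
#' @return `filament_to_json` returns `path` invisibly; `filament_from_json`
#'   returns the restored `filament_model`.
#' @export
filament_to_json <- function(f, path) {
  stopifnot(inherits(f, "filament_model"))
  rec <- list(accession = f$accession, chain_id = f$chain_id,
              residue_numbers = f$residue_numbers,
              backbone = f$backbone$vertices,
              repeats = f$repeats)
  if (!is.null(f$pushoff)) rec$pushoff <- f$pushoff$vertices
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname filament_to_json
#' @export
filament_from_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  filament_model(
    backbone = polygonal_curve(rec$backbone, label = rec$accession),
    residue_numbers = rec$residue_numbers,
    repeats = rec$repeats,
    pushoff = if (!is.null(rec$pushoff)) polygonal_curve(rec$pushoff),
    accession = rec$accession, chain_id = rec$chain_id)
}
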