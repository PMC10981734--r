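#' Read a PDB or mmCIF structure into per-chain atom tables
#'
#' First model only; hydrogens (and deuteriums) are dropped; for alternate
#' locations the highest-occupancy copy of each atom is kept (ties broken by
#' first occurrence). Parsing is delegated to bio3d.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return A named list (by chain id) of data frames with columns `chain`,
#'   `resno`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `o`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path, multi = FALSE),
    error = function(e) stop("could not parse structure file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: ", path)
  elesy <- toupper(trimws(if (!is.null(at$elesy)) at$elesy else ""))
  guess <- toupper(substr(trimws(at$elety), 1L, 1L))
  elesy <- ifelse(is.na(elesy) | elesy == "", guess, elesy)
  keep <- !(elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]
  if (nrow(at) == 0L) stop("no heavy atoms in structure: ", path)
  occ <- if (!is.null(at$o)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
  df <- data.frame(chain = as.character(at$chain), resno = at$resno,
                   resid = as.character(at$resid),
                   elety = trimws(as.character(at$elety)), elesy = elesy,
                   x = at$x, y = at$y, z = at$z, o = occ,
                   stringsAsFactors = FALSE)
  df$chain[is.na(df$chain) | df$chain == ""] <- "A"
  # altloc resolution: keep the highest-occupancy copy per (chain, resno, atom)
  key <- paste(df$chain, df$resno, df$elety, sep = "\r")
  ord <- order(key, -df$o)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$chain, df$resno), , drop = FALSE]
  rownames(df) <- NULL
  split(df, df$chain)
}

#' Fetch a structure by PDB accession into a local cache
#'
#' Downloads `<accession>.pdb` from the RCSB file server unless already
#' cached. Requires network access; offline environments must pre-populate
#' `cache_dir`.
#'
#' @param accession 4-character PDB id.
#' @param cache_dir Directory for cached files.
#' @return Path to the cached file.
#' @export
fetch_structure <- function(accession, cache_dir = file.path(tempdir(), "pdb_cache")) {
  accession <- tolower(accession)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(accession, ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(accession))
    status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                       error = function(e) -1L, warning = function(w) -1L)
    if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      stop("could not fetch '", accession, "' (offline, or accession unknown); ",
           "place the file in ", cache_dir, " manually")
    }
  }
  dest
}

#' Extract the CA backbone of a chain as a filament model
#'
#' CA atoms in residue order form the open polygonal backbone (N- to
#' C-terminus). Gaps in residue numbering are recorded with a warning but
#' the flanking vertices are joined consecutively, as in the underlying
#' polygonal-curve representation.
#'
#' @param chain_atoms One chain's atom table from [read_structure()].
#' @param residue_range Optional `c(first, last)` restriction (inclusive).
#' @param repeats Repeat boundary table, see [repeat_range_table()].
#' @param accession,chain_id Provenance strings (defaulted from the table).
#' @return A `filament_model`.
#' @export
extract_backbone <- function(chain_atoms, residue_range = NULL,
                             repeats = repeat_range_table(),
                             accession = "", chain_id = NULL) {
  ca <- chain_atoms[chain_atoms$elety == "CA", , drop = FALSE]
  if (!is.null(residue_range)) {
    ca <- ca[ca$resno >= residue_range[1] & ca$resno <= residue_range[2], ,
             drop = FALSE]
  }
  ca <- ca[order(ca$resno), , drop = FALSE]
  dup <- duplicated(ca$resno)
  if (any(dup)) ca <- ca[!dup, , drop = FALSE]
  if (nrow(ca) < 2L) stop("chain has fewer than 2 CA atoms in range")
  gaps <- which(diff(ca$resno) > 1L)
  if (length(gaps)) {
    warning(sprintf("numbering gaps after residue(s) %s; vertices joined consecutively",
                    paste(ca$resno[gaps], collapse = ", ")))
  }
  if (is.null(chain_id)) chain_id <- ca$chain[1]
  filament_model(
    backbone = polygonal_curve(as.matrix(ca[, c("x", "y", "z")]),
                               label = paste0(accession, "/", chain_id)),
    residue_numbers = ca$resno, repeats = repeats,
    accession = accession, chain_id = chain_id)
}

#' Build the side-chain push-off curve of a filament
#'
#' One vertex per backbone residue: the position of the `atom_rank`-th
#' farthest non-hydrogen side-chain (R-group) atom from that residue's CA
#' (rank 1 = farthest; higher ranks support robustness re-analysis and fall
#' back to the farthest available atom when the side chain is short).
#' Residues without any R-group heavy atom (glycine) get a vertex
#' interpolated from the flanking residues' push-off vertices; terminal
#' residues without R-group atoms reuse the nearest defined CA-to-push-off
#' offset so that backbone and push-off stay disjoint.
#'
#' @param chain_atoms One chain's atom table from [read_structure()].
#' @param f The `filament_model` whose backbone the push-off accompanies.
#' @param atom_rank Distance rank of the selected R-group atom (1 = farthest).
#' @return A `filament_model` equal to `f` with the `pushoff` slot filled.
#' @export
build_pushoff <- function(chain_atoms, f, atom_rank = 1) {
  stopifnot(inherits(f, "filament_model"), atom_rank >= 1)
  backbone_atoms <- c("N", "CA", "C", "O", "OXT")
  n <- length(f$residue_numbers)
  push <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    res <- chain_atoms[chain_atoms$resno == f$residue_numbers[i], , drop = FALSE]
    rg <- res[!(res$elety %in% backbone_atoms) & !(res$elesy %in% c("H", "D")), ,
              drop = FALSE]
    if (nrow(rg) == 0L) next
    ca <- f$backbone$vertices[i, ]
    d <- sqrt((rg$x - ca[1])^2 + (rg$y - ca[2])^2 + (rg$z - ca[3])^2)
    pick <- order(-d)[min(atom_rank, nrow(rg))]
    push[i, ] <- c(rg$x[pick], rg$y[pick], rg$z[pick])
  }
  missing <- which(is.na(push[, 1]))
  for (i in missing) {
    lo <- max(which(!is.na(push[seq_len(i), 1])), -Inf)
    hi_cand <- which(!is.na(push[, 1]))
    hi <- if (any(hi_cand > i)) min(hi_cand[hi_cand > i]) else Inf
    if (is.finite(lo) && is.finite(hi)) {
      w <- (i - lo) / (hi - lo)
      push[i, ] <- (1 - w) * push[lo, ] + w * push[hi, ]
    } else if (is.finite(lo)) {
      push[i, ] <- f$backbone$vertices[i, ] +
        (push[lo, ] - f$backbone$vertices[lo, ])
    } else if (is.finite(hi)) {
      push[i, ] <- f$backbone$vertices[i, ] +
        (push[hi, ] - f$backbone$vertices[hi, ])
    } else {
      stop("no residue has any R-group heavy atom; cannot build a push-off")
    }
  }
  f$pushoff <- polygonal_curve(push, label = paste0(f$backbone$label, "_pushoff"))
  f
}

#' Stacked-filament assembly
#'
#' A list of filament models (one per rung/chain) plus the symmetric pairs
#' of spatial neighbors found by [find_neighbors()].
#'
#' @param filaments List of `filament_model` objects.
#' @param cutoff Neighbor cutoff in Angstrom (minimal inter-chain CA-CA
#'   distance).
#' @return An object of class `stacked_assembly`.
#' @export
stacked_assembly <- function(filaments, cutoff = 6) {
  stopifnot(length(filaments) >= 1,
            all(vapply(filaments, inherits, logical(1), "filament_model")))
  out <- structure(list(filaments = filaments, neighbor_pairs = NULL,
                        cutoff = cutoff),
                   class = "stacked_assembly")
  out$neighbor_pairs <- find_neighbors(out)
  out
}

#' @export
print.stacked_assembly <- function(x, ...) {
  cat(sprintf("<stacked_assembly> %d filaments, %d neighbor pairs (cutoff %g A)\n",
              length(x$filaments), nrow(x$neighbor_pairs), x$cutoff))
  invisible(x)
}

#' Identify neighboring rungs in an assembly
#'
#' Two filaments are neighbors when their minimal CA-CA inter-chain distance
#' is below the cutoff (adjacent rungs along the fibril axis and/or paired
#' protofilaments).
#'
#' @param assembly A `stacked_assembly`.
#' @param cutoff Distance cutoff in Angstrom; defaults to the assembly's.
#' @return Two-column integer matrix of index pairs (i < j).
#' @export
find_neighbors <- function(assembly, cutoff = NULL) {
  stopifnot(inherits(assembly, "stacked_assembly"))
  if (is.null(cutoff)) cutoff <- assembly$cutoff
  fl <- assembly$filaments
  m <- length(fl)
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (m < 2L) return(pairs)
  for (i in seq_len(m - 1L)) {
    vi <- fl[[i]]$backbone$vertices
    for (j in seq.int(i + 1L, m)) {
      vj <- fl[[j]]$backbone$vertices
      mind2 <- min(vapply(seq_len(nrow(vi)), function(k) {
        min((vj[, 1] - vi[k, 1])^2 + (vj[, 2] - vi[k, 2])^2 +
              (vj[, 3] - vi[k, 3])^2)
      }, numeric(1)))
      if (sqrt(mind2) < cutoff) pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs
}

#' Mean linking number with neighboring filaments
#'
#' The stacked-filament linking of rung `i`: the mean Gauss linking number
#' of filament `i` with each of its identified neighbors. `Lk_s` and its
#' per-residue normalization `Lk_s / N` feed the global classification.
#'
#' @param assembly A `stacked_assembly`.
#' @param i Filament index.
#' @return List with `Lk_s`, `Lk_s_per_N`, `n_neighbors`. With no neighbors
#'   both values are `NA` (ND).
#' @export
stacked_linking <- function(assembly, i) {
  stopifnot(inherits(assembly, "stacked_assembly"))
  pairs <- assembly$neighbor_pairs
  nb <- c(pairs[pairs[, 1] == i, 2], pairs[pairs[, 2] == i, 1])
  f <- assembly$filaments[[i]]
  n <- n_vertices(f$backbone)
  if (length(nb) == 0L) {
    return(list(Lk_s = NA_real_, Lk_s_per_N = NA_real_, n_neighbors = 0L))
  }
  lks <- vapply(nb, function(j) {
    gauss_linking(f$backbone, assembly$filaments[[j]]$backbone)
  }, numeric(1))
  list(Lk_s = mean(lks), Lk_s_per_N = mean(lks) / n,
       n_neighbors = length(nb))
}

#' Read a fibril structure file into a stacked assembly
#'
#' Convenience wrapper: [read_structure()] on every chain, backbone
#' extraction, optional push-off construction, neighbor identification.
#'
#' @param path Structure file.
#' @param residue_range Optional residue restriction applied to every chain.
#' @param with_pushoff Also build per-chain push-off curves.
#' @param atom_rank Push-off atom rank, see [build_pushoff()].
#' @param cutoff Neighbor cutoff in Angstrom.
#' @param repeats Repeat boundary table.
#' @param accession Provenance string (defaults to the file name).
#' @return A `stacked_assembly`.
#' @export
read_assembly <- function(path, residue_range = NULL, with_pushoff = FALSE,
                          atom_rank = 1, cutoff = 6,
                          repeats = repeat_range_table(), accession = NULL) {
  if (is.null(accession)) {
    accession <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                     ignore.case = TRUE)
  }
  chains <- read_structure(path)
  filaments <- lapply(names(chains), function(ch) {
    f <- extract_backbone(chains[[ch]], residue_range = residue_range,
                          repeats = repeats, accession = accession,
                          chain_id = ch)
    if (with_pushoff) f <- build_pushoff(chains[[ch]], f, atom_rank = atom_rank)
    f
  })
  names(filaments) <- names(chains)
  stacked_assembly(filaments, cutoff = cutoff)
}
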