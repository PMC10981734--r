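#' Batch per-structure topological analysis
#'
#' For each structure file: read all chains, extract backbones (and
#' push-offs), compute the global topological summary of the analysis chain
#' (writhe, stacked-filament linking against the other chains, second
#' Vassiliev measure), the ribbon summary, the repeat-linking table and its
#' sign tuple. Per-file failures are logged and the batch continues.
#'
#' @param paths Character vector of PDB/mmCIF paths.
#' @param chain Analysis chain id, or `NULL` for the first chain
#'   (alphabetical) covering the widest resolved range.
#' @param residue_range Optional residue restriction.
#' @param n_projections,seed Second-Vassiliev sampling controls. Each
#'   structure gets a sub-seed derived deterministically from `seed`.
#' @param atom_rank Push-off atom rank.
#' @param neighbor_cutoff Stacking neighbor cutoff (Angstrom).
#' @param repeats Repeat boundary table.
#' @param with_pushoff Build push-offs and ribbon summaries.
#' @return List of class `filament_analysis`: `summaries` (tibble, one row
#'   per structure), `ribbons` (list of `ribbon_summary`), `repeat_tables`,
#'   `tuples`, `errors`, `provenance`.
#' @export
analyze_filaments <- function(paths, chain = NULL, residue_range = NULL,
                              n_projections = 1e4, seed = 1, atom_rank = 1,
                              neighbor_cutoff = 6,
                              repeats = repeat_range_table(),
                              with_pushoff = TRUE) {
  summaries <- NULL
  ribbons <- list(); repeat_tables <- list(); tuples <- list()
  errors <- list()
  for (s in seq_along(paths)) {
    path <- paths[s]
    res <- tryCatch({
      asm <- read_assembly(path, residue_range = residue_range,
                           with_pushoff = with_pushoff,
                           atom_rank = atom_rank, cutoff = neighbor_cutoff,
                           repeats = repeats)
      idx <- if (!is.null(chain) && chain %in% names(asm$filaments)) {
        which(names(asm$filaments) == chain)
      } else {
        widths <- vapply(asm$filaments, function(f) {
          diff(range(f$residue_numbers))
        }, numeric(1))
        which(widths == max(widths))[1]
      }
      f <- asm$filaments[[idx]]
      sub_seed <- (as.integer(seed) + 7919L * s) %% .Machine$integer.max
      sm <- summarize_filament(f, assembly = asm, filament_index = idx,
                               n_projections = n_projections,
                               seed = sub_seed)
      rt <- repeat_linking(f)
      list(id = sm$id, summary = sm, repeat_table = rt,
           tuple = sign_tuple(rt),
           ribbon = if (with_pushoff && !is.null(f$pushoff)) ribbon_summary(f))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[path]] <- conditionMessage(res)
      warning(sprintf("skipping '%s': %s", path, conditionMessage(res)))
      next
    }
    summaries <- rbind(summaries, res$summary)
    repeat_tables[[res$id]] <- res$repeat_table
    tuples[[res$id]] <- res$tuple
    if (!is.null(res$ribbon)) ribbons[[res$id]] <- res$ribbon
  }
  structure(list(summaries = summaries, ribbons = ribbons,
                 repeat_tables = repeat_tables, tuples = tuples,
                 errors = errors,
                 provenance = list(seed = seed,
                                   n_projections = n_projections,
                                   chain = chain, atom_rank = atom_rank,
                                   neighbor_cutoff = neighbor_cutoff,
                                   repeat_table = repeats)),
            class = "filament_analysis")
}

#' Write the per-filament tables of an analysis as CSV + JSON
#'
#' One CSV of global summaries, one of ribbon summaries, one of repeat
#' linking values, plus a JSON provenance block (seed, projections, chain
#' choice, repeat table).
#'
#' @param analysis A `filament_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_analysis <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "filament_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(global = file.path(out_dir, "global_metrics.csv"),
                provenance = file.path(out_dir, "provenance.json"))
  utils::write.csv(analysis$summaries, paths$global, row.names = FALSE)
  if (length(analysis$repeat_tables)) {
    rt <- do.call(rbind, lapply(names(analysis$repeat_tables), function(id) {
      cbind(id = id, as.data.frame(analysis$repeat_tables[[id]]))
    }))
    paths$repeat_linking <- file.path(out_dir, "repeat_linking.csv")
    utils::write.csv(rt, paths$repeat_linking, row.names = FALSE)
  }
  if (length(analysis$ribbons)) {
    rb <- do.call(rbind, lapply(names(analysis$ribbons), function(id) {
      x <- analysis$ribbons[[id]]
      cbind(id = id, region = c("filament", x$regions$region),
            lk = c(x$Lk, x$regions$lk),
            lk_norm = c(x$Lk_per_N, x$regions$lk_per_region))
    }))
    paths$ribbon <- file.path(out_dir, "ribbon_linking.csv")
    utils::write.csv(as.data.frame(rb), paths$ribbon, row.names = FALSE)
  }
  jsonlite::write_json(analysis$provenance, paths$provenance,
                       digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Linking fingerprint of one structure file
#'
#' Computes the residue-resolved linking matrix of the analysis chain and
#' writes it as CSV plus a rendered fingerprint image.
#'
#' @param path Structure file.
#' @param out_prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.png`.
#' @param chain Analysis chain id (`NULL`: widest resolved range).
#' @param stride Matrix stride, see [linking_matrix()].
#' @param residue_range Optional residue restriction.
#' @return Invisibly, list with `matrix`, `csv`, `image`.
#' @export
fingerprint_structure <- function(path, out_prefix, chain = NULL, stride = 1L,
                                  residue_range = NULL) {
  asm <- read_assembly(path, residue_range = residue_range,
                       with_pushoff = FALSE)
  idx <- if (!is.null(chain) && chain %in% names(asm$filaments)) {
    which(names(asm$filaments) == chain)
  } else {
    widths <- vapply(asm$filaments, function(f) diff(range(f$residue_numbers)),
                     numeric(1))
    which(widths == max(widths))[1]
  }
  m <- linking_matrix(asm$filaments[[idx]], stride = stride)
  csv <- paste0(out_prefix, ".csv")
  img <- paste0(out_prefix, ".png")
  write_topology_csv(m, csv)
  render_fingerprint(m, img, title = basename(path))
  invisible(list(matrix = m, csv = csv, image = img))
}
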