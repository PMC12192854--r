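#' Conformational ensembles
#'
#' An `ensemble` holds an ordered set of frames of coordinates (in Angstrom)
#' over a fixed residue selection for one system replicate. Coordinates are
#' stored as a 3-D array `[frame, residue, xyz]`; `residue_ids` carries the
#' author residue numbering (which need not start at 1), and positional
#' indices into the array are 1-based.
#'
#' @param coords numeric array `F x N x 3` of coordinates in Angstrom.
#' @param residue_ids integer vector of length `N`, strictly increasing.
#' @param system,replicate system name and replicate index (metadata).
#' @param frame_interval time between frames (metadata only).
#' @param aligned set to `TRUE` for ensembles whose frames already share a
#'   common coordinate frame (e.g. the synthetic sampler, which adds
#'   displacements to a fixed reference): fluctuation statistics then skip
#'   the rigid-body superposition step, which would otherwise absorb part
#'   of the planted displacement field.
#' @return An object of class `ensemble`.
#' @export
new_ensemble <- function(coords, residue_ids, system = "system",
                         replicate = 1L, frame_interval = NA_real_,
                         aligned = FALSE) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    abort("`coords` must be an F x N x 3 array")
  if (dim(coords)[2] != length(residue_ids))
    abort("length of `residue_ids` must match the residue dimension of `coords`")
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  if (is.unsorted(residue_ids, strictly = TRUE))
    abort("`residue_ids` must be strictly increasing")
  structure(
    list(coords = coords, residue_ids = as.integer(residue_ids),
         system = system, replicate = as.integer(replicate),
         frame_interval = frame_interval, aligned = isTRUE(aligned)),
    class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> system=%s replicate=%d: %d frames x %d residues\n",
              x$system, x$replicate, n_frames(x), n_residues(x)))
  invisible(x)
}

#' @rdname new_ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname new_ensemble
#' @export
n_residues <- function(x) dim(x$coords)[2]

#' Extract one frame as an N x 3 coordinate matrix
#' @param x an `ensemble`.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(x, i) {
  m <- x$coords[i, , , drop = FALSE]
  dim(m) <- dim(x$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

# position of each requested residue_id in the selection, with validation
residue_positions <- function(x, residue_id) {
  pos <- match(residue_id, x$residue_ids)
  if (anyNA(pos))
    abort(paste0("residue(s) not in selection: ",
                 paste(residue_id[is.na(pos)], collapse = ", ")))
  pos
}

#' Read a coordinate ensemble from disk
#'
#' Reads either a multi-model PDB file (all models must share the same atom
#' ordering) or the package's CSV frame-table dialect with columns
#' `frame,residue_id,x,y,z`. For PDB input the selection defaults to C-alpha
#' atoms.
#'
#' @param path path to a multi-model PDB file or a CSV frame table.
#' @param selection_spec atom-name filter for PDB input (default `"CA"`).
#' @param system,replicate metadata attached to the returned ensemble.
#' @return An [new_ensemble()] object.
#' @export
read_ensemble <- function(path, selection_spec = "CA",
                          system = "system", replicate = 1L,
                          aligned = FALSE) {
  if (grepl("\\.(csv|tsv)$", path, ignore.case = TRUE)) {
    return(read_frame_table(path, system = system, replicate = replicate,
                            aligned = aligned))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = selection_spec, verbose = FALSE)
  if (length(sel$atom) == 0L) abort("empty selection")
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  if (any(is.na(xyz)))
    abort("malformed ensemble: inconsistent atom counts across models")
  resno <- pdb$atom$resno[sel$atom]
  nf <- nrow(xyz)
  n <- length(resno)
  coords <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new_ensemble(coords, resno, system = system, replicate = replicate)
}

read_frame_table <- function(path, system = "system", replicate = 1L,
                             aligned = FALSE) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "residue_id", "x", "y", "z")
  if (!all(need %in% names(tab)))
    abort("frame table must have columns frame,residue_id,x,y,z")
  frames <- sort(unique(tab$frame))
  resids <- sort(unique(tab$residue_id))
  nf <- length(frames); n <- length(resids)
  if (nrow(tab) != nf * n)
    abort("malformed ensemble: frames do not share a common residue selection")
  tab <- dplyr::arrange(tab, .data$frame, .data$residue_id)
  coords <- array(NA_real_, c(nf, n, 3))
  coords[, , 1] <- matrix(tab$x, nrow = nf, byrow = TRUE)
  coords[, , 2] <- matrix(tab$y, nrow = nf, byrow = TRUE)
  coords[, , 3] <- matrix(tab$z, nrow = nf, byrow = TRUE)
  new_ensemble(coords, resids, system = system, replicate = replicate,
               aligned = aligned)
}

#' Write an ensemble to disk
#'
#' `write_ensemble()` writes the CSV frame-table dialect;
#' `write_ensemble_pdb()` writes a multi-model C-alpha PDB.
#'
#' @param ensemble an [new_ensemble()] object.
#' @param path output file path.
#' @export
write_ensemble <- function(ensemble, path) {
  nf <- n_frames(ensemble); n <- n_residues(ensemble)
  tab <- tibble(
    frame = rep(seq_len(nf), each = n),
    residue_id = rep(ensemble$residue_ids, nf),
    x = as.vector(t(ensemble$coords[, , 1])),
    y = as.vector(t(ensemble$coords[, , 2])),
    z = as.vector(t(ensemble$coords[, , 3])))
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ensemble, f)
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), ensemble$residue_ids, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Domain maps: residue to structural-region assignment
#'
#' A domain map assigns every residue of the selection to one of the five
#' structural regions `SH3`, `SH2`, `L` (interdomain linker), `SH1N` and
#' `SH1C` (N/C lobes of the catalytic domain). The assignment must be a
#' partition: every residue covered exactly once.
#'
#' @param region_of named list or vector: `region label -> integer vector of
#'   residue ids`, or a two-column data frame with `residue_id` and `region`.
#' @return A tibble of class `domain_map` with columns `residue_id`, `region`.
#' @export
domain_map <- function(region_of) {
  if (is.data.frame(region_of)) {
    tab <- tibble(residue_id = as.integer(region_of$residue_id),
                  region = as.character(region_of$region))
  } else {
    tab <- purrr::imap_dfr(as.list(region_of), function(ids, reg)
      tibble(residue_id = as.integer(ids), region = reg))
  }
  bad <- setdiff(unique(tab$region), REGION_LEVELS)
  if (length(bad))
    abort(paste0("unknown region label(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(tab$residue_id))
    abort("domain map is not a partition: residues assigned more than once")
  tab <- dplyr::arrange(tab, .data$residue_id)
  class(tab) <- c("domain_map", class(tab))
  tab
}

#' Load a domain map from a JSON config
#'
#' The config maps region labels to residue ranges, e.g.
#' `{"SH3": [1, 10], "SH2": [11, 20], ...}` (inclusive ranges), or to
#' explicit residue-id arrays.
#'
#' @param path JSON file path.
#' @param residue_ids optional: selection residue ids to validate coverage
#'   against (total and exclusive).
#' @export
load_domain_map <- function(path, residue_ids = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- purrr::map(cfg, function(v) {
    v <- as.integer(v)
    if (length(v) == 2L && v[2] >= v[1]) seq.int(v[1], v[2]) else v
  })
  dm <- domain_map(reg)
  if (!is.null(residue_ids)) validate_domain_map(dm, residue_ids)
  dm
}

#' @rdname load_domain_map
#' @param map a `domain_map`.
#' @export
validate_domain_map <- function(map, residue_ids) {
  missing <- setdiff(residue_ids, map$residue_id)
  extra <- setdiff(map$residue_id, residue_ids)
  if (length(missing))
    abort(paste0("domain map misses residue(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  if (length(extra))
    abort(paste0("domain map covers residue(s) outside the selection: ",
                 paste(head(extra, 5), collapse = ", ")))
  invisible(map)
}

# region label per position for a given selection
region_vector <- function(map, residue_ids) {
  validate_domain_map(map, residue_ids)
  map$region[match(residue_ids, map$residue_id)]
}

#' System manifests
#'
#' A manifest lists the systems of a study: condition (`apo`, `ATP`, `DAS`),
#' the binary activity label (`1` = active-like, `0` = inactive-like), and
#' the ensemble replicates belonging to each system (file paths, or in-memory
#' ensembles when built by the synthetic generator).
#'
#' @param systems character vector of system names.
#' @param condition character vector in `{apo, ATP, DAS}`.
#' @param label integer vector in `{0, 1}`.
#' @param ensembles list (one entry per system) of file-path vectors or lists
#'   of `ensemble` objects.
#' @return A tibble of class `system_manifest`.
#' @export
system_manifest <- function(systems, condition, label, ensembles = NULL) {
  if (!all(condition %in% c("apo", "ATP", "DAS")))
    abort("condition must be one of apo, ATP, DAS")
  if (!all(label %in% c(0L, 1L))) abort("labels must be binary (0/1)")
  tab <- tibble(system = systems, condition = condition,
                label = as.integer(label),
                ensembles = ensembles %||% vector("list", length(systems)))
  class(tab) <- c("system_manifest", class(tab))
  tab
}

#' @rdname system_manifest
#' @param path JSON manifest path; each entry gives `condition`, `label`,
#'   and `paths` (ensemble files, resolved relative to the manifest).
#' @export
load_manifest <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  man <- system_manifest(
    systems = names(cfg),
    condition = purrr::map_chr(cfg, "condition"),
    label = purrr::map_int(cfg, ~ as.integer(.x$label)),
    ensembles = purrr::map(cfg, ~ resolve(unlist(.x$paths))))
  man$aligned <- purrr::map_lgl(cfg, ~ isTRUE(.x$aligned))
  man
}

# materialize the replicates of one manifest row as ensemble objects
manifest_ensembles <- function(manifest, i) {
  ent <- manifest$ensembles[[i]]
  if (is.null(ent)) abort(paste0("no ensembles for system ", manifest$system[i]))
  if (inherits(ent, "ensemble")) ent <- list(ent)
  aligned <- if ("aligned" %in% names(manifest)) manifest$aligned[i] else FALSE
  purrr::imap(as.list(ent), function(e, k) {
    if (inherits(e, "ensemble")) e
    else read_ensemble(e, system = manifest$system[i], replicate = k,
                       aligned = aligned)
  })
}

#' Export a residue graph to GraphML
#'
#' @param graph a `residue_graph` (see [build_graph()]).
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}
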