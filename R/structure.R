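#' Single-structure models
#'
#' A `structure_model` is an atom table: one row per atom with name, element,
#' coordinates (Angstrom), residue id/name and chain. It is the input of the
#' SASA and interface stages.
#'
#' @param atoms data frame with columns `atom_name`, `element`, `x`, `y`,
#'   `z`, `residue_id`, `residue_name`, `chain_id`.
#' @param source free-text label recording where the model came from.
#' @return A tibble of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "unknown") {
  need <- c("atom_name", "element", "x", "y", "z", "residue_id",
            "residue_name", "chain_id")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    abort(paste0("atom table misses column(s): ", paste(missing, collapse = ", ")))
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    abort("coordinates must be finite")
  tab <- as_tibble(atoms[need])
  tab$residue_id <- as.integer(tab$residue_id)
  attr(tab, "source") <- source
  class(tab) <- c("structure_model", class(tab))
  tab
}

#' @rdname structure_model
#' @param ensemble an [new_ensemble()] object.
#' @param frame frame index to extract.
#' @export
structure_from_frame <- function(ensemble, frame = 1L) {
  xyz <- frame_coords(ensemble, frame)
  structure_model(
    tibble(atom_name = "CA", element = "C",
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
           residue_id = ensemble$residue_ids, residue_name = "ALA",
           chain_id = "A"),
    source = sprintf("%s frame %d", ensemble$system, frame))
}

#' Read a single (or first-model) structure from a PDB file
#'
#' @param path PDB file path.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  structure_model(
    tibble(atom_name = trimws(at$elety), element = trimws(elem),
           x = at$x, y = at$y, z = at$z,
           residue_id = at$resno, residue_name = at$resid,
           chain_id = at$chain),
    source = path)
}

#' Synthetic reference geometry
#'
#' A smooth helix-like curve with approximately 3.8 Angstrom C-alpha spacing:
#' an alpha-helical winding (radius 2.3 A, rise 1.5 A, 100 degrees per
#' residue) carried along a gently curved superhelical axis so that
#' sequence-distant regions still pack against each other. This gives the
#' surface/interface stages plausible packing without requiring a real
#' kinase model.
#'
#' @param n number of residues.
#' @param residue_ids residue numbering (default `1:n`).
#' @return `n x 3` coordinate matrix (Angstrom), rownames = residue ids.
#' @export
reference_curve <- function(n, residue_ids = seq_len(n)) {
  stopifnot(length(residue_ids) == n)
  rise <- 1.5                      # axial rise per residue (A)
  r_minor <- 2.3                   # helix radius (A)
  dtheta <- 100 * pi / 180         # helical twist per residue
  r_major <- 16                    # superhelix radius (A)
  # axis: slow circular arc, arc length `rise` per residue
  phi <- (seq_len(n) - 1) * rise / r_major
  axis <- cbind(r_major * cos(phi), r_major * sin(phi), 0.18 * r_major * phi)
  # local frame along the axis (tangent / normal / binormal)
  tangent <- cbind(-sin(phi), cos(phi), 0.18)
  tangent <- tangent / sqrt(rowSums(tangent^2))
  normal <- cbind(-cos(phi), -sin(phi), 0)
  binormal <- cbind(
    tangent[, 2] * normal[, 3] - tangent[, 3] * normal[, 2],
    tangent[, 3] * normal[, 1] - tangent[, 1] * normal[, 3],
    tangent[, 1] * normal[, 2] - tangent[, 2] * normal[, 1])
  theta <- (seq_len(n) - 1) * dtheta
  xyz <- axis + r_minor * (cos(theta) * normal + sin(theta) * binormal)
  rownames(xyz) <- residue_ids
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' @rdname reference_curve
#' @export
reference_structure <- function(n, residue_ids = seq_len(n)) {
  xyz <- reference_curve(n, residue_ids)
  structure_model(
    tibble(atom_name = "CA", element = "C",
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
           residue_id = residue_ids, residue_name = "ALA", chain_id = "A"),
    source = "synthetic reference curve")
}

#' Domain map for the full-length Src-family kinase construct
#'
#' Region boundaries for the 443-residue full-length construct (residues
#' 60-502): SH3 60-126, SH2 127-229, interdomain linker 230-246, SH1
#' N-lobe 247-350, SH1 C-lobe 351-502. Boundaries are approximate domain
#' assignments for the modeled construct and can be overridden with a
#' custom JSON map.
#'
#' @export
lyn_domain_map <- function() {
  domain_map(list(
    SH3 = 60:126, SH2 = 127:229, L = 230:246,
    SH1N = 247:350, SH1C = 351:502))
}
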