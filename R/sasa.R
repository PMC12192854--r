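# van der Waals radii (Angstrom) used for SASA; element-based table
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.10)

atom_radii <- function(elements) {
  r <- VDW_RADII[toupper(elements)]
  if (anyNA(r))
    abort(paste0("no radius for element(s): ",
                 paste(unique(elements[is.na(r)]), collapse = ", ")))
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-section spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure: for every atom, test points on
#' the probe-inflated sphere (radius r + probe) are checked for burial by
#' neighboring atoms' inflated spheres; the exposed fraction scaled by
#' 4*pi*(r+probe)^2 is the atom's SASA. Radii come from an element-based
#' table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.10 A).
#'
#' @param structure a [structure_model()].
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points sphere test points per atom.
#' @return list of class `sasa_result`: `atom` tibble (per-atom area),
#'   `residue` tibble (per-residue sum), `total`, `probe`, `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L) {
  xyz <- cbind(structure$x, structure$y, structure$z)
  R <- atom_radii(structure$element) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbor lists via one pairwise distance matrix (desk-scale structures)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  atom_tab <- tibble(atom = seq_len(n), atom_name = structure$atom_name,
                     element = structure$element,
                     residue_id = structure$residue_id, sasa = area)
  res_tab <- atom_tab |>
    dplyr::group_by(.data$residue_id) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
  out <- list(atom = atom_tab, residue = res_tab, total = sum(area),
              probe = probe, n_points = n_points)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, %d residues, total %.1f A^2 (probe %.2f A, %d points)\n",
              nrow(x$atom), nrow(x$residue), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Interface residues from buried surface area
#'
#' Splits the structure into two parts, computes each part's SASA in
#' isolation and in the complex, and calls residues whose SASA drops by more
#' than `threshold` upon association interface residues
#' (`delta_sasa = SASA(isolated part) - SASA(complex)`).
#'
#' @param structure a [structure_model()].
#' @param region_a,region_b disjoint residue-id vectors defining the two
#'   parts.
#' @param threshold buried-area cutoff in Angstrom^2.
#' @param probe,n_points passed to [sasa()].
#' @return Tibble `residue_id`, `part`, `delta_sasa`, `interface` (logical),
#'   with the interface residue ids in `attr(, "interface")`.
#' @export
interface_residues <- function(structure, region_a, region_b, threshold = 1.0,
                               probe = 1.4, n_points = 960L) {
  if (!length(region_a) || !length(region_b))
    abort("both partition sides must be non-empty")
  if (length(intersect(region_a, region_b)))
    abort("partition sides overlap")
  part_of <- function(ids) structure[structure$residue_id %in% ids, ]
  sub_a <- part_of(region_a); sub_b <- part_of(region_b)
  if (!nrow(sub_a) || !nrow(sub_b)) abort("empty partition side")
  complex_s <- structure[structure$residue_id %in% c(region_a, region_b), ]
  s_a <- sasa(sub_a, probe, n_points)$residue
  s_b <- sasa(sub_b, probe, n_points)$residue
  s_c <- sasa(complex_s, probe, n_points)$residue
  iso <- dplyr::bind_rows(
    dplyr::mutate(s_a, part = "A"), dplyr::mutate(s_b, part = "B"))
  out <- dplyr::left_join(iso, s_c, by = "residue_id",
                          suffix = c("_iso", "_complex")) |>
    dplyr::transmute(residue_id = .data$residue_id, part = .data$part,
                     delta_sasa = .data$sasa_iso - .data$sasa_complex) |>
    dplyr::mutate(interface = .data$delta_sasa > threshold) |>
    dplyr::arrange(.data$residue_id)
  attr(out, "interface") <- out$residue_id[out$interface]
  attr(out, "threshold") <- threshold
  out
}

#' Interdomain interface set for one system
#'
#' Runs [interface_residues()] for every pair of structural regions in the
#' domain map and returns the union of interface residues, i.e. the residues
#' buried at any interdomain interface of this structure.
#'
#' @param structure a [structure_model()].
#' @param map a [domain_map()].
#' @param threshold buried-area cutoff in Angstrom^2.
#' @param probe,n_points passed to [sasa()].
#' @return Tibble `pair`, `residue_id`, `delta_sasa` for all called
#'   interface residues; union ids in `attr(, "interface")`.
#' @export
interdomain_interfaces <- function(structure, map, threshold = 1.0,
                                   probe = 1.4, n_points = 960L) {
  regions <- intersect(REGION_LEVELS, unique(map$region))
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    ids_a <- map$residue_id[map$region == pr[1]]
    ids_b <- map$residue_id[map$region == pr[2]]
    res <- interface_residues(structure, ids_a, ids_b, threshold,
                              probe, n_points)
    res <- res[res$interface, c("residue_id", "delta_sasa")]
    if (nrow(res)) res$pair <- paste(pr, collapse = "-")
    res
  })
  out <- if (nrow(rows)) rows[, c("pair", "residue_id", "delta_sasa")] else
    tibble(pair = character(), residue_id = integer(), delta_sasa = double())
  attr(out, "interface") <- sort(unique(out$residue_id))
  out
}

#' Ligand-pocket surface area
#'
#' Pocket residues are all residues with any atom within `radius` of any
#' ligand atom; the pocket surface area is their summed per-residue SASA.
#' By default the ligand is excluded from the occlusion set (the area of the
#' unliganded pocket surface); `include_ligand = TRUE` adds the ligand atoms
#' as occluders instead.
#'
#' @param structure a [structure_model()].
#' @param ligand matrix of ligand coordinates, or a data frame with
#'   `x`, `y`, `z` and (if `include_ligand`) `element`.
#' @param radius pocket definition radius in Angstrom.
#' @param include_ligand occlude the pocket surface with the ligand atoms.
#' @param probe,n_points passed to [sasa()].
#' @return Pocket area (Angstrom^2) with the pocket residue ids in
#'   `attr(, "pocket_residues")`.
#' @export
pocket_surface_area <- function(structure, ligand, radius = 5.0,
                                include_ligand = FALSE, probe = 1.4,
                                n_points = 960L) {
  lig_xyz <- if (is.data.frame(ligand)) cbind(ligand$x, ligand$y, ligand$z)
             else as.matrix(ligand)
  if (!nrow(lig_xyz)) abort("ligand is empty")
  pocket <- pocket_residues(structure, lig_xyz, radius)
  if (!length(pocket)) {
    warn("no residue within the pocket radius; returning 0")
    out <- 0
    attr(out, "pocket_residues") <- integer(0)
    return(out)
  }
  occ <- structure
  if (include_ligand) {
    elem <- if (is.data.frame(ligand) && "element" %in% names(ligand))
      ligand$element else rep("C", nrow(lig_xyz))
    lig_tab <- tibble(atom_name = "LIG", element = elem,
                      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                      residue_id = max(structure$residue_id) + 1L,
                      residue_name = "LIG", chain_id = "X")
    occ <- structure_model(dplyr::bind_rows(as_tibble(structure), lig_tab),
                           source = "with ligand")
  }
  res <- sasa(occ, probe, n_points)$residue
  area <- sum(res$sasa[res$residue_id %in% pocket])
  attr(area, "pocket_residues") <- pocket
  area
}

pocket_residues <- function(structure, lig_xyz, radius) {
  if (radius <= 0) {
    warn("non-positive pocket radius selects nothing")
    return(integer(0))
  }
  xyz <- cbind(structure$x, structure$y, structure$z)
  mind2 <- apply(lig_xyz, 1, function(l)
    (xyz[, 1] - l[1])^2 + (xyz[, 2] - l[2])^2 + (xyz[, 3] - l[3])^2)
  near <- apply(mind2 <= radius^2, 1, any)
  sort(unique(structure$residue_id[near]))
}

#' Ligand-contact occupancy over an ensemble
#'
#' Fraction of frames in which each residue has its C-alpha within `radius`
#' of any ligand atom.
#'
#' @param ensemble protein [new_ensemble()].
#' @param ligand ligand coordinates per frame: an `ensemble`, or a list of
#'   matrices (one per frame).
#' @param radius contact radius in Angstrom.
#' @return Tibble `residue_id`, `occupancy` in `[0, 1]`.
#' @export
ligand_contact_occupancy <- function(ensemble, ligand, radius = 5.0) {
  nf <- n_frames(ensemble)
  lig_frame <- function(f) {
    m <- if (inherits(ligand, "ensemble")) frame_coords(ligand, f)
         else ligand[[f]]
    if (is.null(m) || !nrow(m)) abort(paste0("missing ligand in frame ", f))
    m
  }
  if (inherits(ligand, "ensemble") && n_frames(ligand) != nf)
    abort("ligand frame count does not match the ensemble")
  if (!inherits(ligand, "ensemble") && length(ligand) != nf)
    abort("ligand frame count does not match the ensemble")
  hits <- matrix(FALSE, nf, n_residues(ensemble))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ensemble, f)
    lg <- lig_frame(f)
    d2 <- apply(lg, 1, function(l)
      (xyz[, 1] - l[1])^2 + (xyz[, 2] - l[2])^2 + (xyz[, 3] - l[3])^2)
    hits[f, ] <- apply(matrix(d2, nrow = nrow(xyz)) <= radius^2, 1, any)
  }
  tibble(residue_id = ensemble$residue_ids, occupancy = colMeans(hits))
}
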