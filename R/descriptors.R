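#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` over the fit selection (determinant-corrected
#' so no reflection is introduced).
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @param fit_selection row indices used for the fit (default all).
#' @return list with `coords` (all mobile atoms transformed), `rmsd` (over
#'   the fit selection), `rotation`, and the two centroids.
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  sel <- fit_selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3) abort("degenerate fit: need at least 3 fit atoms")
  if (max(sel) > nrow(mobile) || max(sel) > nrow(reference))
    abort("fit selection out of range")
  Pm <- mobile[sel, , drop = FALSE]
  Pr <- reference[sel, , drop = FALSE]
  cm <- colMeans(Pm); cr <- colMeans(Pr)
  Pmc <- sweep(Pm, 2, cm); Prc <- sweep(Pr, 2, cr)
  sv_chk <- svd(Prc)$d
  if (sv_chk[2] < 1e-8 * max(sv_chk[1], 1))
    abort("degenerate fit: fit atoms are (nearly) collinear")
  A <- crossprod(Pmc, Prc)           # 3x3
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  out <- sweep(mobile, 2, cm) %*% R
  out <- sweep(out, 2, cr, "+")
  fitted_sel <- out[sel, , drop = FALSE]
  list(coords = out,
       rmsd = sqrt(mean(rowSums((fitted_sel - Pr)^2))),
       rotation = R, mobile_centroid = cm, reference_centroid = cr)
}

# plain RMSD between two already-aligned coordinate sets
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# fit every frame of an ensemble onto a reference matrix; returns the
# ensemble with transformed coordinates
fit_frames <- function(ensemble, reference, fit_selection = NULL) {
  for (f in seq_len(n_frames(ensemble))) {
    ensemble$coords[f, , ] <-
      superpose(frame_coords(ensemble, f), reference, fit_selection)$coords
  }
  ensemble
}

# iterated fit-to-mean (two rounds); returns list(ensemble, mean).
# Pre-aligned ensembles skip the superposition unless force = TRUE.
fit_to_mean <- function(ensemble, iterations = 2L, force = FALSE) {
  if (isTRUE(ensemble$aligned) && !force)
    return(list(ensemble = ensemble,
                mean = apply(ensemble$coords, c(2, 3), mean)))
  ref <- frame_coords(ensemble, 1L)
  for (it in seq_len(iterations)) {
    ensemble <- fit_frames(ensemble, ref)
    ref <- apply(ensemble$coords, c(2, 3), mean)
  }
  list(ensemble = ensemble, mean = ref)
}

#' Per-frame RMSD series
#'
#' RMSD of every frame against a reference after least-squares fitting.
#' The fit uses the whole selection (global-fit convention); when `domain`
#' is given the deviation is measured over that region's residues only, so
#' domain RMSD reflects the region's mobility relative to the fitted core.
#'
#' @param ensemble an [new_ensemble()].
#' @param reference N x 3 matrix; default the first frame.
#' @param domain optional region label; requires `map`.
#' @param map a [domain_map()] (needed when `domain` is given).
#' @param fit `"global"` (default) fits on the whole selection; `"domain"`
#'   fits on the region itself.
#' @return Tibble `frame`, `rmsd` (Angstrom) with attributes `system`,
#'   `domain`.
#' @export
rmsd_series <- function(ensemble, reference = NULL, domain = NULL, map = NULL,
                        fit = c("global", "domain")) {
  fit <- match.arg(fit)
  reference <- reference %||% frame_coords(ensemble, 1L)
  if (nrow(reference) != n_residues(ensemble))
    abort("reference does not match the ensemble selection")
  meas_sel <- seq_len(n_residues(ensemble))
  if (!is.null(domain)) {
    if (is.null(map)) abort("`map` is required for domain-restricted RMSD")
    if (!domain %in% map$region) abort(paste0("unknown domain: ", domain))
    reg <- region_vector(map, ensemble$residue_ids)
    meas_sel <- which(reg == domain)
  }
  fit_sel <- if (fit == "global") seq_len(n_residues(ensemble)) else meas_sel
  vals <- purrr::map_dbl(seq_len(n_frames(ensemble)), function(f) {
    s <- superpose(frame_coords(ensemble, f), reference, fit_sel)
    coord_rmsd(s$coords[meas_sel, , drop = FALSE],
               reference[meas_sel, , drop = FALSE])
  })
  out <- tibble(frame = seq_len(n_frames(ensemble)), rmsd = vals)
  attr(out, "system") <- ensemble$system
  attr(out, "domain") <- domain %||% "all"
  out
}

#' Per-residue RMSF profile
#'
#' Root mean square fluctuation about the ensemble mean structure, after
#' superposing all frames onto the mean (fit-to-mean iterated twice; the
#' fixed point is stable).
#'
#' @param ensemble an [new_ensemble()].
#' @return Tibble `residue_id`, `rmsf` (Angstrom), class `flex_profile`.
#' @export
rmsf_profile <- function(ensemble) {
  fm <- fit_to_mean(ensemble)
  dev2 <- matrix(0, n_frames(ensemble), n_residues(ensemble))
  for (f in seq_len(n_frames(ensemble))) {
    dev2[f, ] <- rowSums((frame_coords(fm$ensemble, f) - fm$mean)^2)
  }
  out <- tibble(residue_id = ensemble$residue_ids, rmsf = sqrt(colMeans(dev2)))
  attr(out, "system") <- ensemble$system
  class(out) <- c("flex_profile", class(out))
  out
}

#' Flexibility difference between two systems
#'
#' `delta_rmsf = reference - other` per residue; positive values indicate
#' higher flexibility in the reference (e.g. wildtype) system.
#'
#' @param wt,mut `flex_profile` tibbles aligned on `residue_id`.
#' @export
delta_rmsf <- function(wt, mut) {
  if (!identical(wt$residue_id, mut$residue_id))
    abort("profiles are not aligned on residue_id")
  out <- tibble(residue_id = wt$residue_id, delta_rmsf = wt$rmsf - mut$rmsf)
  attr(out, "pair") <- paste0(attr(wt, "system") %||% "a", "-",
                              attr(mut, "system") %||% "b")
  out
}

#' Geometric feature descriptors
#'
#' `feat_distance()`, `feat_angle()` and `feat_centroid_distance()` build
#' descriptor definitions consumed by [geometry_series()]: C-alpha pair
#' distances (Angstrom), three-point angles (degrees, e.g. the R-spine
#' angle), and region-centroid distances.
#'
#' @param name descriptor name (unique within a spec).
#' @param i,j,k residue ids.
#' @param region_a,region_b region labels (require a domain map at
#'   evaluation time).
#' @export
feat_distance <- function(name, i, j)
  list(name = name, type = "distance", residues = c(i, j))

#' @rdname feat_distance
#' @export
feat_angle <- function(name, i, j, k)
  list(name = name, type = "angle", residues = c(i, j, k))

#' @rdname feat_distance
#' @export
feat_centroid_distance <- function(name, region_a, region_b)
  list(name = name, type = "centroid_distance", regions = c(region_a, region_b))

#' Per-frame geometry table
#'
#' Evaluates a list of descriptor definitions (see [feat_distance()]) over
#' every frame of an ensemble.
#'
#' @param ensemble an [new_ensemble()].
#' @param spec list of descriptor definitions.
#' @param map a [domain_map()]; required for centroid descriptors.
#' @return Tibble with a `frame` column plus one column per descriptor.
#' @export
geometry_series <- function(ensemble, spec, map = NULL) {
  reg <- if (!is.null(map)) region_vector(map, ensemble$residue_ids)
  cols <- purrr::map(spec, function(d) {
    switch(d$type,
      distance = {
        p <- residue_positions(ensemble, d$residues)
        sqrt(rowSums((ensemble$coords[, p[1], ] - ensemble$coords[, p[2], ])^2))
      },
      angle = {
        p <- residue_positions(ensemble, d$residues)
        v1 <- ensemble$coords[, p[1], ] - ensemble$coords[, p[2], ]
        v2 <- ensemble$coords[, p[3], ] - ensemble$coords[, p[2], ]
        cosang <- rowSums(v1 * v2) /
          sqrt(rowSums(v1^2) * rowSums(v2^2))
        acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      },
      centroid_distance = {
        if (is.null(reg)) abort("centroid descriptors need a domain map")
        pa <- which(reg == d$regions[1]); pb <- which(reg == d$regions[2])
        if (!length(pa) || !length(pb))
          abort(paste0("region not in map: ", paste(d$regions, collapse = "/")))
        ca <- apply(ensemble$coords[, pa, , drop = FALSE], c(1, 3), mean)
        cb <- apply(ensemble$coords[, pb, , drop = FALSE], c(1, 3), mean)
        sqrt(rowSums((ca - cb)^2))
      },
      abort(paste0("unknown descriptor type: ", d$type)))
  })
  names(cols) <- purrr::map_chr(spec, "name")
  dplyr::bind_cols(tibble(frame = seq_len(n_frames(ensemble))), cols)
}

#' Representative structure by PAM clustering
#'
#' Clusters frames on their pairwise C-alpha RMSD with partitioning around
#' medoids (PAM), chooses k by maximum mean silhouette over `k_candidates`,
#' and returns the medoid of the most populated cluster. For large ensembles
#' frames are subsampled evenly (`max_frames`) before the quadratic RMSD
#' matrix is built.
#'
#' @param ensemble an [new_ensemble()].
#' @param k_candidates candidate cluster counts (default 2-8).
#' @param max_frames cap on frames entering the pairwise RMSD matrix.
#' @return list: `frame` (index into the original ensemble), `k`,
#'   `silhouette`, `cluster_sizes`, `degenerate` flag.
#' @export
representative_structure <- function(ensemble, k_candidates = 2:8,
                                     max_frames = 100L) {
  nf <- n_frames(ensemble)
  idx <- if (nf > max_frames)
    unique(round(seq(1, nf, length.out = max_frames))) else seq_len(nf)
  m <- length(idx)
  D <- matrix(0, m, m)
  for (a in seq_len(m - 1)) {
    ca <- frame_coords(ensemble, idx[a])
    for (b in (a + 1):m) {
      D[a, b] <- D[b, a] <-
        superpose(frame_coords(ensemble, idx[b]), ca)$rmsd
    }
  }
  if (max(D) < 1e-9) {
    warn("all frames identical: degenerate clustering, returning frame 1")
    return(list(frame = 1L, k = NA_integer_, silhouette = NA_real_,
                cluster_sizes = m, degenerate = TRUE))
  }
  ks <- k_candidates[k_candidates < m]
  if (!length(ks)) abort("not enough frames for any candidate k")
  fits <- purrr::map(ks, function(k)
    cluster::pam(stats::as.dist(D), k = k, diss = TRUE))
  sil <- purrr::map_dbl(fits, function(f)
    mean(cluster::silhouette(f$clustering, stats::as.dist(D))[, "sil_width"]))
  best <- fits[[which.max(sil)]]
  sizes <- table(best$clustering)
  top_cluster <- as.integer(names(sizes)[which.max(sizes)])
  medoid_local <- best$medoids[top_cluster]
  list(frame = idx[medoid_local], k = ks[which.max(sil)],
       silhouette = max(sil), cluster_sizes = as.integer(sizes),
       degenerate = FALSE)
}

#' Compare two value distributions (Wilcoxon)
#'
#' Paired samples use the two-sided Wilcoxon signed-rank test; unpaired (or
#' unequal-length) samples fall back to the rank-sum test, and the
#' substitution is recorded in the `method` column.
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @return Tibble `statistic`, `p_value`, `method`.
#' @export
compare_distributions <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    abort("paired comparison requires equal lengths")
  if (paired && all(a - b == 0))
    abort("degenerate test: all paired differences are zero")
  if (paired) {
    ht <- wilcox.test(a, b, paired = TRUE, exact = NULL)
    method <- "wilcoxon-signed-rank"
  } else {
    ht <- wilcox.test(a, b, paired = FALSE, exact = NULL)
    method <- "wilcoxon-rank-sum"
  }
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = method)
}
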