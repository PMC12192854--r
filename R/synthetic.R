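#' Planted coupling specifications
#'
#' A `coupling_spec` describes the correlation structure planted into a
#' synthetic ensemble: residues in the same structural region share
#' `intra_block_corr`; designated hub residues couple across regions with
#' `hub_cross_corr`; every other pair sits at `baseline_corr`. Displacements
#' are scaled by `fluctuation_scale` (Angstrom).
#'
#' @param intra_block_corr within-region correlation, in (0, 1).
#' @param hub_residues residue ids acting as cross-region couplers.
#' @param hub_cross_corr hub-to-other-region correlation, in (0, 1).
#' @param baseline_corr background correlation, `>= 0`.
#' @param fluctuation_scale per-axis displacement SD in Angstrom.
#' @export
coupling_spec <- function(intra_block_corr = 0.85, hub_residues = integer(0),
                          hub_cross_corr = 0.85, baseline_corr = 0.1,
                          fluctuation_scale = 1.0) {
  stopifnot(intra_block_corr > 0, intra_block_corr < 1,
            hub_cross_corr > 0, hub_cross_corr < 1,
            baseline_corr >= 0, fluctuation_scale > 0)
  if (!(baseline_corr < hub_cross_corr && hub_cross_corr <= intra_block_corr))
    abort("need baseline_corr < hub_cross_corr <= intra_block_corr")
  structure(list(intra_block_corr = intra_block_corr,
                 hub_residues = as.integer(hub_residues),
                 hub_cross_corr = hub_cross_corr,
                 baseline_corr = baseline_corr,
                 fluctuation_scale = fluctuation_scale),
            class = "coupling_spec")
}

#' Build a planted residue correlation matrix
#'
#' Entry (i, j) is `intra_block_corr` when i and j share a region,
#' `hub_cross_corr` when either is a hub residue and the regions differ, and
#' `baseline_corr` otherwise; the diagonal is 1. Block-plus-hub constructions
#' can be slightly indefinite, so the matrix is projected to the nearest
#' positive semi-definite matrix by eigenvalue clipping (floor 1e-8) and the
#' diagonal re-normalized to 1.
#'
#' @param map a [domain_map()] covering the residues.
#' @param spec a [coupling_spec()].
#' @return N x N correlation matrix, dimnames = residue ids.
#' @export
build_planted_covariance <- function(map, spec) {
  ids <- map$residue_id
  n <- length(ids)
  reg <- map$region
  same <- outer(reg, reg, "==")
  C <- matrix(spec$baseline_corr, n, n)
  C[same] <- spec$intra_block_corr
  if (length(spec$hub_residues)) {
    hub <- ids %in% spec$hub_residues
    cross_hub <- (outer(hub, rep(TRUE, n), "&") |
                    outer(rep(TRUE, n), hub, "&")) & !same
    C[cross_hub] <- spec$hub_cross_corr
  }
  diag(C) <- 1
  C <- psd_project(C)
  dimnames(C) <- list(ids, ids)
  C
}

# nearest-PSD repair: clip eigenvalues at a small floor, rebuild, restore a
# unit diagonal so the result is still a correlation matrix
psd_project <- function(C, floor = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= 0) return(C)
  vals <- pmax(e$values, floor)
  C2 <- e$vectors %*% (vals * t(e$vectors))
  C2 <- stats::cov2cor(C2)
  e2 <- eigen(C2, symmetric = TRUE, only.values = TRUE)$values
  if (min(e2) < -1e-6) abort("covariance remains indefinite after clipping")
  (C2 + t(C2)) / 2
}

#' Sample a synthetic ensemble from a planted correlation
#'
#' Per-axis residue displacements are drawn from a zero-mean multivariate
#' normal with the given residue correlation, independently for x, y and z
#' (so the planted residue correlation matrix is analytically equal to the
#' expected DCCM), scaled by `fluctuation_scale` and added to the reference
#' C-alpha positions.
#'
#' @param covariance N x N residue correlation matrix.
#' @param reference N x 3 coordinate matrix or a `structure_model` of N
#'   C-alpha atoms.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed (reproducible for a fixed seed).
#' @param fluctuation_scale per-axis displacement SD in Angstrom.
#' @param residue_ids residue numbering; defaults to covariance dimnames.
#' @param system,replicate metadata.
#' @return An [new_ensemble()].
#' @export
sample_ensemble <- function(covariance, reference, n_frames, seed = 1L,
                            fluctuation_scale = 1.0,
                            residue_ids = NULL, system = "synthetic",
                            replicate = 1L) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (inherits(reference, "structure_model"))
    reference <- cbind(reference$x, reference$y, reference$z)
  n <- nrow(covariance)
  if (nrow(reference) != n)
    abort("covariance dimension must equal reference residue count")
  if (is.null(residue_ids))
    residue_ids <- as.integer(rownames(covariance) %||% seq_len(n))
  e <- eigen(covariance, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  coords <- array(NA_real_, c(n_frames, n, 3))
  for (ax in 1:3) {
    z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
    coords[, , ax] <- fluctuation_scale * (z %*% t(L)) +
      matrix(reference[, ax], n_frames, n, byrow = TRUE)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  new_ensemble(coords, residue_ids, system = system, replicate = replicate,
               aligned = TRUE)
}

#' Default synthetic domain map
#'
#' A compact five-region map used by the synthetic study sets: SH3 1-10,
#' SH2 11-20, linker 21-22, SH1N 23-30, SH1C 31-40 (40 residues), scalable
#' by an integer factor.
#'
#' @param scale integer multiplier on the region sizes.
#' @export
synthetic_domain_map <- function(scale = 1L) {
  sizes <- c(SH3 = 10L, SH2 = 10L, L = 2L, SH1N = 8L, SH1C = 10L) * scale
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  domain_map(purrr::map2(starts, ends, seq.int) |> setNames(names(sizes)))
}

#' Backbone (integration-hub) correlation construction
#'
#' A positive-semi-definite-feasible way to plant recoverable allosteric
#' hubs. A flat construction in which a hub correlates above the network
#' edge threshold (0.8) with several mutually weakly-coupled regions cannot
#' be a correlation matrix: correlations along any two-edge path are bounded
#' below (`cor(x,z) >= cos(acos(cor(x,y)) + acos(cor(y,z)))`), so the
#' nearest-PSD projection destroys exactly the couplings being planted.
#' Instead, hubs here form a cross-region clique (`hub_hub`) anchored into
#' their own regions through two flanking anchor residues (`hub_anchor`),
#' with the implied second- and third-shell correlations planted at their
#' consistency bounds (`hub_own`, `hub_foreign_anchor`, `anchor_cross`,
#' `anchor_foreign`, `hub_foreign`). At the 0.8 edge threshold this yields
#' blocks connected only through the hub backbone: hubs carry the
#' cross-domain shortest paths (high betweenness) and form the
#' minimum-purity (integration) module.
#'
#' @param map a [domain_map()].
#' @param hub_residues hub residue ids (each needs two same-region
#'   neighbours to act as anchors).
#' @param intra_block_corr within-region correlation.
#' @param baseline_corr background cross-region correlation.
#' @param hub_hub,hub_anchor,hub_own,hub_foreign_anchor,hub_foreign,anchor_cross,anchor_foreign
#'   shell correlations (see Description).
#' @return N x N correlation matrix (PSD after eigenvalue clipping),
#'   with `attr(, "anchors")` listing each hub's anchor residues.
#' @export
build_backbone_covariance <- function(map, hub_residues,
                                      intra_block_corr = 0.87,
                                      baseline_corr = 0.10,
                                      hub_hub = 0.93, hub_anchor = 0.86,
                                      hub_own = 0.60,
                                      hub_foreign_anchor = 0.62,
                                      hub_foreign = 0.33,
                                      anchor_cross = 0.42,
                                      anchor_foreign = 0.20) {
  ids <- map$residue_id
  reg <- map$region
  n <- length(ids)
  hub_residues <- as.integer(hub_residues)
  if (!all(hub_residues %in% ids)) abort("hub residues outside the map")
  anchors <- purrr::map(hub_residues, function(h) {
    own <- ids[reg == reg[match(h, ids)] & ids != h]
    if (length(own) < 2) abort("each hub needs two same-region anchors")
    own[order(abs(own - h))][1:2]
  })
  is_hub <- ids %in% hub_residues
  is_anchor <- ids %in% unlist(anchors)
  same <- outer(reg, reg, "==")
  C <- matrix(baseline_corr, n, n)
  C[same] <- intra_block_corr
  cross <- !same
  an <- (outer(is_anchor, !is_anchor & !is_hub, "&") |
           outer(!is_anchor & !is_hub, is_anchor, "&")) & cross
  C[an] <- anchor_foreign
  C[outer(is_anchor, is_anchor, "&") & cross] <- anchor_cross
  for (hi in seq_along(hub_residues)) {
    h <- match(hub_residues[hi], ids)
    own <- which(reg == reg[h]) |> setdiff(h)
    C[h, own] <- C[own, h] <- hub_own
    a <- match(anchors[[hi]], ids)
    C[h, a] <- C[a, h] <- hub_anchor
    fn <- which(reg != reg[h] & !is_hub & !is_anchor)
    C[h, fn] <- C[fn, h] <- hub_foreign
    for (fj in seq_along(hub_residues)[-hi]) {
      fa <- match(anchors[[fj]], ids)
      C[h, fa] <- C[fa, h] <- hub_foreign_anchor
    }
  }
  C[outer(is_hub, is_hub, "&") & cross] <- hub_hub
  diag(C) <- 1
  C <- psd_project(C)
  dimnames(C) <- list(ids, ids)
  attr(C, "anchors") <- setNames(anchors, hub_residues)
  C
}

#' Generate a synthetic study set
#'
#' Builds a manifest of active-like and inactive-like systems with planted
#' correlation structure: all systems share tight intra-region coupling,
#' but only active-like systems carry the cross-region hub backbone
#' ([build_backbone_covariance()]), in which the designated hub residues
#' bridge the structural regions; inactive-like systems have their hubs
#' decoupled to the baseline (flat [build_planted_covariance()]), emulating
#' fragmented mutant networks. The default design mirrors a mutational
#' study: 2 active-like and 4 inactive-like systems, 3 replicates each.
#'
#' @param config optional list overriding any of the defaults returned by
#'   `default_study_config()`.
#' @param seed root seed; per-system/replicate seeds are derived from it.
#' @return list with `manifest` (ensembles attached), `map`, `hub_residues`,
#'   `reference`, and the expanded `config`.
#' @export
generate_study_set <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_study_config(), config)
  if (!any(cfg$labels == 1L) || !any(cfg$labels == 0L))
    abort("need at least one active-like and one inactive-like system")
  map <- cfg$map %||% synthetic_domain_map()
  ref <- reference_curve(nrow(map), map$residue_id)
  cov_active <- build_backbone_covariance(
    map, cfg$hub_residues, intra_block_corr = cfg$rho_intra,
    baseline_corr = cfg$rho0)
  # inactive-like systems: hubs decoupled to (just above) baseline
  cov_inactive <- build_planted_covariance(
    map, coupling_spec(cfg$rho_intra, cfg$hub_residues,
                       max(cfg$rho_hub_inactive, cfg$rho0 + 1e-6),
                       cfg$rho0, cfg$fluctuation_scale))
  ensembles <- purrr::imap(setNames(cfg$labels, cfg$systems), function(lab, sys) {
    cov <- if (lab == 1L) cov_active else cov_inactive
    purrr::map(seq_len(cfg$replicates), function(r) {
      s <- seed + 7919L * match(sys, cfg$systems) + 101L * r
      sample_ensemble(cov, ref, cfg$n_frames, seed = s,
                      fluctuation_scale = cfg$fluctuation_scale,
                      residue_ids = map$residue_id, system = sys, replicate = r)
    })
  })
  manifest <- system_manifest(cfg$systems, cfg$conditions, cfg$labels,
                              ensembles = unname(ensembles))
  list(manifest = manifest, map = map, hub_residues = cfg$hub_residues,
       reference = ref, config = cfg)
}

#' @rdname generate_study_set
#' @export
default_study_config <- function() {
  list(
    systems = c("WT", "WT-ATP", "E290K", "I364N", "K275A-ATP", "WT-DAS"),
    conditions = c("apo", "ATP", "apo", "apo", "ATP", "DAS"),
    labels = c(1L, 1L, 0L, 0L, 0L, 0L),
    replicates = 3L,
    n_frames = 400L,
    map = NULL,                          # synthetic_domain_map() when NULL
    hub_residues = c(5L, 15L, 25L, 35L), # one per SH3 / SH2 / SH1N / SH1C
    rho_intra = 0.87,
    rho0 = 0.10,
    rho_hub_inactive = 0.10,
    fluctuation_scale = 1.0)
}

#' Generate a synthetic 16-feature table for the state classifier
#'
#' Gaussian features with a configurable informative subset: informative
#' features have class means separated by `effect_size` pooled standard
#' deviations; the remainder are uninformative noise. Class imbalance is set
#' through `n_frames_per_class` (scalar for balanced classes, or
#' `c(active, inactive)`).
#'
#' @param n_frames_per_class frames per class; length 1 or 2
#'   (active-like, inactive-like).
#' @param effect_size class-mean separation d in pooled-SD units (>= 0).
#' @param n_informative number of informative features (0-16).
#' @param seed RNG seed.
#' @return Tibble with 16 feature columns, `label` (1 active-like,
#'   0 inactive-like) and `system`; informative feature names in
#'   `attr(, "informative")`.
#' @export
generate_feature_table <- function(n_frames_per_class, effect_size = 3,
                                   n_informative = 7, seed = 1L) {
  if (effect_size < 0) abort("effect_size must be >= 0")
  stopifnot(n_informative >= 0, n_informative <= 16)
  n <- rep_len(as.integer(n_frames_per_class), 2L)
  feat_names <- sprintf("feature_%02d", 1:16)
  informative <- feat_names[seq_len(n_informative)]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  lab <- rep(c(1L, 0L), n)
  X <- matrix(stats::rnorm(sum(n) * 16), sum(n), 16,
              dimnames = list(NULL, feat_names))
  shift <- effect_size * (lab - 0.5)          # +d/2 vs -d/2 per class
  for (f in informative) X[, f] <- X[, f] + shift
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  out <- as_tibble(X)
  out$label <- lab
  out$system <- ifelse(lab == 1L, "synthetic-active", "synthetic-inactive")
  attr(out, "informative") <- informative
  out
}

#' Write a synthetic study set to disk
#'
#' Writes CSV frame tables per replicate, a JSON manifest and a JSON domain
#' map, mirroring what the generator holds in memory.
#'
#' @param study result of [generate_study_set()].
#' @param dir output directory (created if needed).
#' @export
write_study_set <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- study$manifest
  entries <- purrr::map(seq_len(nrow(man)), function(i) {
    paths <- purrr::map_chr(manifest_ensembles(man, i), function(e) {
      p <- sprintf("%s_rep%d.csv", gsub("[^A-Za-z0-9]+", "_", e$system),
                   e$replicate)
      write_ensemble(e, file.path(dir, p))
      p
    })
    list(condition = man$condition[i], label = man$label[i], paths = paths,
         aligned = TRUE)
  })
  names(entries) <- man$system
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ranges <- study$map |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(lo = min(.data$residue_id), hi = max(.data$residue_id))
  jsonlite::write_json(
    setNames(purrr::map2(ranges$lo, ranges$hi, c), ranges$region),
    file.path(dir, "domain_map.json"))
  invisible(dir)
}
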