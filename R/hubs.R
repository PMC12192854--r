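#' Correlation between residue centrality and conformational state
#'
#' For residue r with betweenness vector `b_r` across systems and binary
#' activity labels `y` (1 = active-like), the point correlation
#' `rho_r = cor(b_r, y)` quantifies how strongly the residue's network
#' centrality tracks the functional state. Residues with zero-variance
#' centrality get `rho_r = 0` and are flagged.
#'
#' @param B numeric matrix residues x systems of betweenness values
#'   (rownames = residue ids).
#' @param y binary label vector, one per system (at least one per class).
#' @return Tibble `residue_id`, `rho`, `zero_variance`.
#' @export
centrality_state_correlation <- function(B, y) {
  if (length(unique(y)) < 2) abort("need both classes in y")
  if (ncol(B) != length(y)) abort("B columns must align with y")
  sds <- apply(B, 1, sd)
  rho <- rep(0, nrow(B))
  ok <- sds > 0
  rho[ok] <- apply(B[ok, , drop = FALSE], 1, function(b) cor(b, y))
  tibble(residue_id = as.integer(rownames(B)), rho = rho,
         zero_variance = !ok)
}

#' Module-mixing scores
#'
#' For residue r in system s the module-mixing index is
#' `M_{r,s} = 1 - purity(module of r in s)` when r belongs to that system's
#' integration module and 0 otherwise, so recurrent membership in mixed
#' (low-purity) modules is rewarded. The mean over systems is
#' `mu_r = (1/N) sum_s M_{r,s}`.
#'
#' @param partitions named list of `community_partition`, one per system.
#' @param residue_ids all residues of the selection.
#' @return list: `M` (residues x systems matrix), `mu` tibble
#'   (`residue_id`, `mu`).
#' @export
module_mixing <- function(partitions, residue_ids) {
  M <- matrix(0, length(residue_ids), length(partitions),
              dimnames = list(residue_ids, names(partitions)))
  for (s in seq_along(partitions)) {
    p <- partitions[[s]]
    if (is.null(p)) abort("missing partition for a manifest system")
    im <- p$integration_module
    if (is.na(im)) next
    pur <- p$modules$purity[match(im, p$modules$module)]
    members <- p$membership$residue_id[p$membership$module == im]
    M[as.character(members), s] <- 1 - pur
  }
  list(M = M,
       mu = tibble(residue_id = as.integer(residue_ids),
                   mu = unname(rowMeans(M))))
}

#' Interface frequency across systems
#'
#' Counts in how many systems each residue sits at an interdomain interface
#' (`k_r`) and normalizes by the number of systems (`f_r = k_r / N`).
#'
#' @param interface_sets list (one per system) of interface residue-id
#'   vectors.
#' @param residue_ids all residues of the selection.
#' @return Tibble `residue_id`, `k`, `f`.
#' @export
interface_frequency <- function(interface_sets, residue_ids) {
  k <- rowSums(vapply(interface_sets,
                      function(s) residue_ids %in% s,
                      logical(length(residue_ids))))
  tibble(residue_id = as.integer(residue_ids), k = as.integer(k),
         f = k / length(interface_sets))
}

#' Interface-weighted allosteric-hub score
#'
#' Combines state-tracking centrality, module mixing and interface
#' enrichment: `mix_weighted_corr_r = rho_r * mu_r` and
#' `score_r = mix_weighted_corr_r * (1 + f_r)`. Residues with a score
#' strictly greater than `hub_threshold` are flagged as allosteric hubs.
#'
#' @param rho,mu,f aligned numeric vectors (see
#'   [centrality_state_correlation()], [module_mixing()],
#'   [interface_frequency()]).
#' @param residue_ids residue numbering.
#' @param hub_threshold hub cutoff on the interface-weighted score.
#' @return Tibble `residue_id`, `rho`, `mu`, `mix_weighted_corr`, `f`,
#'   `interface_weighted_score`, `is_hub`.
#' @export
interface_weighted_score <- function(rho, mu, f, residue_ids = seq_along(rho),
                                     hub_threshold = 0.5) {
  stopifnot(length(rho) == length(mu), length(mu) == length(f))
  mix <- rho * mu
  score <- mix * (1 + f)
  tibble(residue_id = as.integer(residue_ids), rho = rho, mu = mu,
         mix_weighted_corr = mix, f = f,
         interface_weighted_score = score,
         is_hub = score > hub_threshold)
}

#' End-to-end hub scoring for a study
#'
#' Runs the full network stage for every system of a manifest: per-replicate
#' DCCMs averaged per system, correlation network at the edge threshold,
#' Louvain communities with purity and integration module, betweenness,
#' interface sets on each system's representative (medoid) structure, and
#' the interface-weighted score combining them. The auxiliary unified score
#' `consistency_r * rho_r * mu_r` is reported alongside but does not enter
#' the interface-weighted score.
#'
#' @param manifest a [system_manifest()] with ensembles attached or
#'   resolvable.
#' @param map a [domain_map()].
#' @param edge_threshold correlation threshold for network edges.
#' @param hub_threshold hub cutoff on the interface-weighted score.
#' @param interface_threshold buried-area cutoff (Angstrom^2).
#' @param length_transform betweenness path-length transform.
#' @param consistency_grid thresholds for the consistency score (set to
#'   `NULL` to skip).
#' @param n_connectors connector-list size for the consistency score.
#' @param seed RNG seed (Louvain restarts).
#' @param sasa_points sphere points for the interface SASA stage.
#' @param medoid_frames frame cap for medoid extraction.
#' @return list of class `hub_analysis`: `hub_table` (per-residue score
#'   table), `betweenness` (matrix), `partitions`, `dccms`, `graphs`,
#'   `interfaces`, `medoid_frames`, `y`.
#' @export
score_hubs <- function(manifest, map, edge_threshold = 0.8,
                       hub_threshold = 0.5, interface_threshold = 1.0,
                       length_transform = "neglog",
                       consistency_grid = c(0.70, 0.75, 0.80, 0.85, 0.90),
                       n_connectors = 25L, seed = 1L, sasa_points = 480L,
                       medoid_frames = 40L) {
  if (length(unique(manifest$label)) < 2)
    abort("need at least one system per class for hub scoring")
  ids <- map$residue_id
  systems <- manifest$system
  dccms <- list(); graphs <- list(); partitions <- list()
  interfaces <- list(); medoids <- list()
  B <- matrix(0, length(ids), length(systems),
              dimnames = list(ids, systems))
  consistency <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(systems)) {
    ens_list <- manifest_ensembles(manifest, i)
    validate_domain_map(map, ens_list[[1]]$residue_ids)
    d <- average_dccm(purrr::map(ens_list, dccm))
    g <- build_graph(d, edge_threshold, length_transform)
    # per-system seed derived from the system name so results do not depend
    # on manifest ordering
    p <- detect_communities(g, map,
                            seed = seed + sum(utf8ToInt(systems[i])) %% 10000L)
    b <- betweenness_profile(g)
    B[, i] <- b$betweenness[match(ids, b$residue_id)]
    # representative structure of the first replicate for interface calling
    rep1 <- ens_list[[1]]
    med <- representative_structure(rep1, max_frames = medoid_frames)
    iface <- interdomain_interfaces(structure_from_frame(rep1, med$frame),
                                    map, interface_threshold,
                                    n_points = sasa_points)
    dccms[[systems[i]]] <- d
    graphs[[systems[i]]] <- g
    partitions[[systems[i]]] <- p
    interfaces[[systems[i]]] <- attr(iface, "interface")
    medoids[[systems[i]]] <- med$frame
    if (!is.null(consistency_grid)) {
      cons <- threshold_consistency(d, consistency_grid, n_connectors,
                                    length_transform)
      consistency <- consistency + cons$consistency
    }
  }
  consistency <- consistency / length(systems)
  rho_tab <- centrality_state_correlation(B, manifest$label)
  mix <- module_mixing(partitions, ids)
  freq <- interface_frequency(interfaces, ids)
  tab <- interface_weighted_score(rho_tab$rho, mix$mu$mu, freq$f,
                                  residue_ids = ids,
                                  hub_threshold = hub_threshold)
  tab$k <- freq$k
  tab$consistency <- unname(consistency)
  tab$unified_score <- tab$consistency * tab$rho * tab$mu
  tab$region <- region_vector(map, ids)
  tab$zero_variance_centrality <- rho_tab$zero_variance
  class(tab) <- c("hub_score_table", class(tab))
  out <- list(hub_table = tab, betweenness = B, partitions = partitions,
              dccms = dccms, graphs = graphs, interfaces = interfaces,
              medoid_frames = medoids, y = manifest$label,
              edge_threshold = edge_threshold, hub_threshold = hub_threshold)
  class(out) <- "hub_analysis"
  out
}

#' @export
print.hub_analysis <- function(x, ...) {
  cat(sprintf("<hub_analysis> %d systems, %d residues, %d hubs (score > %.2f)\n",
              ncol(x$betweenness), nrow(x$hub_table),
              sum(x$hub_table$is_hub), x$hub_threshold))
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.hub_analysis <- function(x, ...) as_tibble(x$hub_table)

#' @exportS3Method broom::glance
glance.hub_analysis <- function(x, ...) {
  tibble(n_systems = ncol(x$betweenness), n_residues = nrow(x$hub_table),
         n_hubs = sum(x$hub_table$is_hub),
         edge_threshold = x$edge_threshold,
         hub_threshold = x$hub_threshold)
}
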