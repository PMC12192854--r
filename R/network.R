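#' Dynamic cross-correlation matrix (DCCM)
#'
#' Normalized covariance of residue displacement vectors about the mean:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, values in `[-1, 1]`.
#' By default frames are C-alpha aligned to the ensemble mean first, except
#' for ensembles flagged as pre-aligned (the synthetic sampler generates
#' displacements in a common frame, where removing rigid-body degrees of
#' freedom would only distort the planted field).
#'
#' @param ensemble an [new_ensemble()] with `F >= 2`.
#' @param fit superpose frames onto the iterated mean first; default
#'   (`NULL`) fits unless the ensemble is pre-aligned.
#' @return N x N matrix of class `dccm_matrix` (symmetric, unit diagonal),
#'   dimnames = residue ids, attributes `system`, `residue_ids`.
#' @export
dccm <- function(ensemble, fit = NULL) {
  if (n_frames(ensemble) < 2) abort("need at least 2 frames")
  fit <- fit %||% !isTRUE(ensemble$aligned)
  if (fit) {
    ensemble <- fit_to_mean(ensemble, force = TRUE)$ensemble
  }
  nf <- n_frames(ensemble); n <- n_residues(ensemble)
  S <- matrix(0, n, n)
  for (ax in 1:3) {
    D <- ensemble$coords[, , ax]
    D <- sweep(D, 2, colMeans(D))
    S <- S + crossprod(D)
  }
  v <- diag(S)
  zero <- v <= 0
  if (any(zero)) {
    warn(paste0(sum(zero), " zero-variance residue(s): rows/columns set to 0"))
    v[zero] <- 1
  }
  C <- S / sqrt(outer(v, v))
  if (any(zero)) {
    C[zero, ] <- 0
    C[, zero] <- 0
  }
  diag(C) <- 1
  C <- pmin(pmax((C + t(C)) / 2, -1), 1)
  dimnames(C) <- list(ensemble$residue_ids, ensemble$residue_ids)
  attr(C, "system") <- ensemble$system
  attr(C, "residue_ids") <- ensemble$residue_ids
  class(C) <- c("dccm_matrix", class(C))
  C
}

#' Average DCCMs element-wise
#'
#' Replicate handling for a system: DCCM per replicate, then element-wise
#' mean.
#'
#' @param dccms list of `dccm_matrix` of equal dimension.
#' @export
average_dccm <- function(dccms) {
  stopifnot(length(dccms) >= 1)
  M <- Reduce(`+`, purrr::map(dccms, unclass)) / length(dccms)
  attributes(M) <- attributes(dccms[[1]])
  M
}

#' @exportS3Method broom::tidy
tidy.dccm_matrix <- function(x, ...) {
  ids <- attr(x, "residue_ids")
  tibble(residue_i = rep(ids, times = length(ids)),
         residue_j = rep(ids, each = length(ids)),
         correlation = as.vector(unclass(x)))
}

#' Similarity between two DCCMs
#'
#' Pearson correlation over the off-diagonal upper triangles, with a
#' two-sided parametric test; non-significant pairs can be flagged when
#' rendering cross-system similarity matrices.
#'
#' @param a,b `dccm_matrix` objects of equal dimension.
#' @param alpha significance level for the `significant` flag.
#' @return Tibble `r`, `p_value`, `significant`.
#' @export
dccm_similarity <- function(a, b, alpha = 0.05) {
  if (!all(dim(a) == dim(b))) abort("DCCM dimensions differ")
  ut <- upper.tri(a, diag = FALSE)
  va <- unclass(a)[ut]; vb <- unclass(b)[ut]
  if (sd(va) == 0 || sd(vb) == 0)
    abort("undefined correlation: constant matrix")
  ht <- stats::cor.test(va, vb, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ht$estimate), p_value = ht$p.value,
         significant = ht$p.value < alpha)
}

#' Build the residue correlation network
#'
#' Undirected weighted graph over residues from the upper triangle of a
#' DCCM: an edge joins i and j iff `|C_ij| > threshold` (strict). Edge
#' weight is `|C_ij|`; the path length used for betweenness is the chosen
#' transform of the correlation (default `-log|c|`, so strong couplings are
#' short).
#'
#' @param dccm a `dccm_matrix`.
#' @param threshold edge threshold in (0, 1).
#' @param length_transform `"neglog"` (`-log|c|`), `"1minus"` (`1 - |c|`),
#'   or `"unweighted"` (all lengths 1).
#' @return Object of class `residue_graph`: `graph` (igraph over the
#'   non-isolated residues), `residue_ids` (all residues of the DCCM),
#'   `node_residues` (residues present in the graph), `threshold`.
#' @export
build_graph <- function(dccm, threshold = 0.8,
                        length_transform = c("neglog", "1minus", "unweighted")) {
  length_transform <- match.arg(length_transform)
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  ids <- attr(dccm, "residue_ids") %||% as.integer(rownames(dccm))
  M <- unclass(dccm)
  ut <- which(upper.tri(M) & abs(M) > threshold, arr.ind = TRUE)
  edges <- tibble(
    from = ids[ut[, 1]], to = ids[ut[, 2]],
    corr = M[ut], weight = abs(M[ut]))
  edges$length <- switch(length_transform,
    neglog = pmax(-log(edges$weight), 1e-12),
    `1minus` = pmax(1 - edges$weight, 1e-12),
    unweighted = rep(1, nrow(edges)))
  node_residues <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    dplyr::mutate(edges, from = as.character(.data$from),
                  to = as.character(.data$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(node_residues)))
  out <- list(graph = g, residue_ids = ids, node_residues = node_residues,
              threshold = threshold, length_transform = length_transform)
  class(out) <- "residue_graph"
  out
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> |c| > %.2f: %d/%d residues, %d edges\n",
              x$threshold, length(x$node_residues), length(x$residue_ids),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Louvain communities with module purity
#'
#' Louvain community detection on the |c|-weighted graph (best of
#' `restarts` runs by modularity, seeded for reproducibility). Module purity
#' is the fraction of a module's residues belonging to its dominant
#' structural region; residues absent from the graph (no retained edge) are
#' recorded as unassigned.
#'
#' @param graph a `residue_graph`.
#' @param map a [domain_map()] covering the graph's residues.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed; restart r uses `seed + r`.
#' @param restarts number of Louvain restarts.
#' @param min_module_size minimum size for integration-module eligibility.
#' @return Object of class `community_partition`: `membership` tibble
#'   (`residue_id`, `module`, `region`), `modules` tibble (`module`, `size`,
#'   `purity`, `dominant_region`), `integration_module` id, `unassigned`
#'   residue ids, `modularity`.
#' @export
detect_communities <- function(graph, map, resolution = 1.0, seed = 1L,
                               restarts = 10L, min_module_size = 4L) {
  if (igraph::ecount(graph$graph) == 0) abort("empty graph")
  w <- igraph::E(graph$graph)$weight
  best <- NULL
  for (r in seq_len(restarts)) {
    cl <- withr::with_seed(seed + r, igraph::cluster_louvain(
      graph$graph, weights = w, resolution = resolution))
    if (is.null(best) ||
        igraph::modularity(cl) > igraph::modularity(best)) best <- cl
  }
  memb <- tibble(
    residue_id = as.integer(igraph::V(graph$graph)$name),
    module = as.integer(igraph::membership(best)))
  memb$region <- region_vector_loose(map, memb$residue_id)
  modules <- memb |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      size = dplyr::n(),
      dominant_region = names(which.max(table(.data$region))),
      purity = max(table(.data$region)) / dplyr::n(),
      .groups = "drop")
  out <- list(
    membership = memb, modules = modules,
    unassigned = setdiff(graph$residue_ids, graph$node_residues),
    modularity = igraph::modularity(best),
    min_module_size = min_module_size)
  out$integration_module <- tryCatch(integration_module(out),
                                     error = function(e) NA_integer_)
  class(out) <- "community_partition"
  out
}

# region lookup that tolerates a map larger than the residue set
region_vector_loose <- function(map, residue_ids) {
  reg <- map$region[match(residue_ids, map$residue_id)]
  if (anyNA(reg)) abort("domain map does not cover all graph residues")
  reg
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d modules, modularity %.3f, integration module %s, %d unassigned\n",
              nrow(x$modules), x$modularity, x$integration_module,
              length(x$unassigned)))
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.community_partition <- function(x, ...) x$membership

#' @exportS3Method broom::glance
glance.community_partition <- function(x, ...) {
  tibble(n_modules = nrow(x$modules), modularity = x$modularity,
         integration_module = x$integration_module,
         integration_purity =
           x$modules$purity[match(x$integration_module, x$modules$module)],
         n_unassigned = length(x$unassigned))
}

#' Integration module of a partition
#'
#' The module with minimum purity among modules of at least
#' `min_module_size` residues (avoiding trivially impure dimers); ties are
#' broken by larger size, then lower module id.
#'
#' @param partition a `community_partition`.
#' @param min_module_size minimum eligible size; defaults to the value
#'   recorded in the partition.
#' @return Module id.
#' @export
integration_module <- function(partition, min_module_size = NULL) {
  min_size <- min_module_size %||% partition$min_module_size %||% 4L
  elig <- partition$modules[partition$modules$size >= min_size, ]
  if (!nrow(elig)) abort("no module of eligible size")
  elig <- elig[order(elig$purity, -elig$size, elig$module), ]
  elig$module[1]
}

#' Betweenness centrality profile
#'
#' Shortest-path betweenness on the correlation network using the graph's
#' path lengths, normalized by `(n-1)(n-2)/2` over the graph's node count.
#' Residues absent from the graph get 0.
#'
#' @param graph a `residue_graph`.
#' @return Tibble `residue_id`, `betweenness` covering every residue of the
#'   underlying DCCM.
#' @export
betweenness_profile <- function(graph) {
  b <- igraph::betweenness(graph$graph,
                           weights = igraph::E(graph$graph)$length,
                           normalized = TRUE)
  out <- tibble(residue_id = graph$residue_ids, betweenness = 0)
  idx <- match(as.integer(names(b)), out$residue_id)
  out$betweenness[idx] <- unname(b)
  out
}

#' Top connector residues
#'
#' The `n` residues with the highest betweenness; ties broken by residue id.
#'
#' @param profile result of [betweenness_profile()].
#' @param n number of connectors.
#' @return Integer vector of residue ids.
#' @export
top_connectors <- function(profile, n = 25L) {
  ord <- order(-profile$betweenness, profile$residue_id)
  profile$residue_id[ord][seq_len(min(n, nrow(profile)))]
}

#' Threshold-consistency score
#'
#' Rebuilds the network over a grid of correlation thresholds and scores
#' each residue by the fraction of thresholds at which it ranks among the
#' top-`n` betweenness connectors. Thresholds yielding an empty graph are
#' skipped with a warning.
#'
#' @param dccm a `dccm_matrix`.
#' @param thresholds threshold grid in (0, 1).
#' @param n connector count per threshold.
#' @param length_transform passed to [build_graph()].
#' @return Tibble `residue_id`, `consistency` in `[0, 1]`.
#' @export
threshold_consistency <- function(dccm, thresholds = c(0.70, 0.75, 0.80, 0.85, 0.90),
                                  n = 25L,
                                  length_transform = "neglog") {
  ids <- attr(dccm, "residue_ids") %||% as.integer(rownames(dccm))
  counts <- setNames(numeric(length(ids)), ids)
  used <- 0L
  for (th in thresholds) {
    g <- build_graph(dccm, th, length_transform)
    if (igraph::ecount(g$graph) == 0) {
      warn(sprintf("threshold %.2f yields an empty graph; skipped", th))
      next
    }
    used <- used + 1L
    top <- top_connectors(betweenness_profile(g), n)
    counts[as.character(top)] <- counts[as.character(top)] + 1
  }
  if (used == 0L) abort("all thresholds yield empty graphs")
  tibble(residue_id = ids, consistency = unname(counts) / used)
}
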