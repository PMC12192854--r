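#' Default pipeline configuration
#'
#' Thresholds follow the analysis conventions: network edges at
#' `|c| > 0.8`, hubs at interface-weighted score `> 0.5`, interface residues
#' at `delta-SASA > 1.0` Angstrom^2, ligand pockets at 5 Angstrom. All
#' randomness derives from one root `seed`, expanded per stage.
#'
#' @param out_dir output directory.
#' @param seed root seed.
#' @export
default_run_config <- function(out_dir = tempfile("allonet_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    manifest = NULL,           # path to manifest.json; NULL -> synthetic
    domain_map = NULL,         # path to domain_map.json; NULL -> synthetic
    study = list(),            # overrides for default_study_config()
    edge_threshold = 0.8,
    hub_threshold = 0.5,
    interface_threshold = 1.0,
    pocket_radius = 5.0,
    length_transform = "neglog",
    consistency_grid = c(0.70, 0.75, 0.80, 0.85, 0.90),
    n_connectors = 25L,
    sasa_points = 480L,
    medoid_frames = 40L,
    classifier = list(n_trees = 500L, smote_ratio = 0.5, smote_k = 5L,
                      train_frac = 0.8),
    stages = c(descriptors = TRUE, pca = TRUE, network = TRUE,
               hubs = TRUE, classify = TRUE))
}

#' Run the full ensemble-to-allostery pipeline
#'
#' Orchestrates synthesis (or loading) of ensembles, flexibility
#' descriptors, essential-dynamics PCA, DCCMs and their similarity matrix,
#' correlation networks with communities and centrality, interface-weighted
#' hub scoring, and the state classifier, writing one CSV/JSON per stage
#' plus a run log into `config$out_dir`. Reruns with the same configuration
#' and seed produce byte-identical CSV outputs.
#'
#' @param config list overriding entries of [default_run_config()], or a
#'   path to a JSON file with the same fields.
#' @return list of class `pipeline_run` with all stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_run_config(), config)
  stages <- cfg$stages
  if (isTRUE(stages[["hubs"]]) && !isTRUE(stages[["network"]]))
    abort("stage dependency: hubs requires network")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = cfg$seed, started = "fixed-run",
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              package_version = as.character(utils::packageVersion("allonet")),
              config = cfg[setdiff(names(cfg), "stages")])
  # --- inputs ---------------------------------------------------------------
  if (is.null(cfg$manifest)) {
    study <- generate_study_set(cfg$study, seed = cfg$seed)
    manifest <- study$manifest
    map <- study$map
    log$input <- "synthetic study set"
  } else {
    manifest <- load_manifest(cfg$manifest)
    map <- load_domain_map(cfg$domain_map)
    study <- NULL
    log$input <- cfg$manifest
  }
  out <- list(config = cfg, manifest = manifest, map = map, study = study)
  path <- function(f) file.path(cfg$out_dir, f)
  all_ens <- purrr::map(seq_len(nrow(manifest)),
                        function(i) manifest_ensembles(manifest, i))
  names(all_ens) <- manifest$system
  # --- descriptors ----------------------------------------------------------
  if (isTRUE(stages[["descriptors"]])) {
    rmsf_tab <- purrr::imap_dfr(all_ens, function(reps, sys)
      purrr::imap_dfr(reps, function(e, r)
        dplyr::mutate(rmsf_profile(e), system = sys, replicate = r)))
    readr::write_csv(rmsf_tab, path("rmsf.csv"))
    rmsd_tab <- purrr::imap_dfr(all_ens, function(reps, sys)
      purrr::imap_dfr(reps, function(e, r)
        dplyr::mutate(rmsd_series(e), system = sys, replicate = r)))
    readr::write_csv(rmsd_tab, path("rmsd.csv"))
    out$rmsf <- rmsf_tab
    out$rmsd <- rmsd_tab
  }
  # --- pca ------------------------------------------------------------------
  if (isTRUE(stages[["pca"]])) {
    pca_sum <- purrr::imap_dfr(all_ens, function(reps, sys) {
      p <- covariance_and_modes(reps[[1]])
      glance(p)
    })
    readr::write_csv(pca_sum, path("pca_summary.csv"))
    out$pca_summary <- pca_sum
  }
  # --- network + hubs -------------------------------------------------------
  if (isTRUE(stages[["network"]])) {
    hub <- score_hubs(
      manifest, map,
      edge_threshold = cfg$edge_threshold,
      hub_threshold = cfg$hub_threshold,
      interface_threshold = cfg$interface_threshold,
      length_transform = cfg$length_transform,
      consistency_grid = cfg$consistency_grid,
      n_connectors = cfg$n_connectors,
      seed = cfg$seed + 1000L,
      sasa_points = cfg$sasa_points,
      medoid_frames = cfg$medoid_frames)
    out$hubs <- hub
    # DCCM similarity across systems
    sys <- manifest$system
    sim <- purrr::map_dfr(utils::combn(seq_along(sys), 2, simplify = FALSE),
                          function(pr) {
      s <- dccm_similarity(hub$dccms[[pr[1]]], hub$dccms[[pr[2]]])
      dplyr::mutate(s, system_a = sys[pr[1]], system_b = sys[pr[2]],
                    .before = 1)
    })
    readr::write_csv(sim, path("dccm_similarity.csv"))
    parts <- purrr::imap_dfr(hub$partitions, function(p, s)
      dplyr::mutate(p$membership, system = s))
    readr::write_csv(parts, path("partitions.csv"))
    cent <- as_tibble(hub$betweenness, rownames = "residue_id")
    readr::write_csv(cent, path("betweenness.csv"))
    if (isTRUE(stages[["hubs"]]))
      readr::write_csv(as_tibble(hub$hub_table), path("hub_scores.csv"))
    out$dccm_similarity <- sim
  }
  # --- classifier -----------------------------------------------------------
  if (isTRUE(stages[["classify"]])) {
    spec <- synthetic_feature_spec(map, seed = cfg$seed)
    feats <- assemble_features(manifest, spec, map)
    fit <- do.call(train_classifier,
                   c(list(table = feats, seed = cfg$seed + 2000L),
                     cfg$classifier))
    readr::write_csv(glance(fit), path("classifier_summary.csv"))
    readr::write_csv(tidy(fit), path("classifier_per_class.csv"))
    readr::write_csv(feature_importance(fit, "gini"),
                     path("importance_gini.csv"))
    out$classifier <- fit
  }
  jsonlite::write_json(log, path("run_log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d systems -> %s\n", nrow(x$manifest),
              x$config$out_dir))
  if (!is.null(x$hubs)) print(x$hubs)
  if (!is.null(x$classifier)) print(x$classifier)
  invisible(x)
}
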