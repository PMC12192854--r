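#' @exportS3Method ggplot2::autoplot
autoplot.dccm_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$residue_i, .data$residue_j,
                                 fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#01665e", limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue", fill = "correlation",
                  title = attr(object, "system"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_pca <- function(object, n_components = 10, ...) {
  tidy(object) |>
    dplyr::slice_head(n = n_components) |>
    ggplot2::ggplot(ggplot2::aes(.data$component, .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "explained variance",
                  title = object$system)
}

#' @exportS3Method ggplot2::autoplot
autoplot.state_classifier <- function(object, ...) {
  roc <- pROC::roc(response = object$test$y, predictor = object$test$prob,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  tibble(fpr = 1 - roc$specificities, tpr = roc$sensitivities) |>
    dplyr::arrange(.data$fpr, .data$tpr) |>
    ggplot2::ggplot(ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' Flexibility profile plot
#'
#' @param profile a `flex_profile` (see [rmsf_profile()]) or a
#'   [delta_rmsf()] table.
#' @param map optional [domain_map()] for region shading.
#' @export
plot_rmsf <- function(profile, map = NULL) {
  ycol <- if ("rmsf" %in% names(profile)) "rmsf" else "delta_rmsf"
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(.data$residue_id, .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = paste0(gsub("_", "-", ycol), " (Å)"))
  if (!is.null(map)) {
    bounds <- map |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(lo = min(.data$residue_id), hi = max(.data$residue_id))
    p <- p + ggplot2::geom_vline(xintercept = bounds$hi + 0.5,
                                 linetype = "dashed", colour = "grey70")
  }
  if (ycol == "delta_rmsf")
    p <- p + ggplot2::geom_hline(yintercept = 0, colour = "grey50")
  p
}

#' Hub score plot
#'
#' Interface-weighted score per residue with the hub threshold and hub
#' residues highlighted.
#'
#' @param hub_table a `hub_score_table` (from [score_hubs()]).
#' @param hub_threshold threshold line to draw.
#' @export
plot_hub_scores <- function(hub_table, hub_threshold = 0.5) {
  ggplot2::ggplot(hub_table,
                  ggplot2::aes(.data$residue_id,
                               .data$interface_weighted_score,
                               colour = .data$region)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$residue_id, yend = 0)) +
    ggplot2::geom_point(data = function(d) d[d$is_hub, ], size = 2) +
    ggplot2::geom_hline(yintercept = hub_threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "interface-weighted score",
                  colour = "region")
}
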