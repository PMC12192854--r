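#' Essential dynamics: PCA of C-alpha fluctuations
#'
#' Frames are superposed onto the ensemble mean structure (same convention
#' as [rmsf_profile()]), the 3N x 3N covariance of the fluctuations is built
#' with 1/F (population) normalization, and its symmetric eigendecomposition
#' gives the collective modes. Eigenvalues below zero (numerical noise) are
#' clipped to 0.
#'
#' @param ensemble an [new_ensemble()] with at least 2 frames.
#' @param fit superpose frames onto the mean first; default (`NULL`) fits
#'   unless the ensemble is pre-aligned.
#' @return Object of class `ensemble_pca`: `values` (eigenvalues, A^2,
#'   descending), `vectors` (3N x 3N, orthonormal columns), `fractions`
#'   (explained variance), `mean` (N x 3), `projections` (F x 3N),
#'   `residue_ids`, `system`.
#' @export
covariance_and_modes <- function(ensemble, fit = NULL) {
  if (n_frames(ensemble) < 2) abort("need at least 2 frames for PCA")
  fit <- fit %||% !isTRUE(ensemble$aligned)
  if (fit) {
    fm <- fit_to_mean(ensemble, force = TRUE)
    ensemble <- fm$ensemble
    mu <- fm$mean
  } else {
    mu <- apply(ensemble$coords, c(2, 3), mean)
  }
  nf <- n_frames(ensemble); n <- n_residues(ensemble)
  # rows = frames, columns residue-major (x1,y1,z1,x2,...)
  X <- matrix(NA_real_, nf, 3 * n)
  for (f in seq_len(nf)) X[f, ] <- as.vector(t(frame_coords(ensemble, f)))
  Xc <- sweep(X, 2, as.vector(t(mu)))
  C <- crossprod(Xc) / nf
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  fractions <- if (sum(vals) > 0) vals / sum(vals) else rep(0, length(vals))
  out <- list(values = vals, vectors = e$vectors, fractions = fractions,
              mean = mu, projections = Xc %*% e$vectors,
              residue_ids = ensemble$residue_ids, system = ensemble$system)
  class(out) <- "ensemble_pca"
  out
}

#' @export
print.ensemble_pca <- function(x, ...) {
  cat(sprintf("<ensemble_pca> system=%s: %d modes, PC1 %.1f%% of variance\n",
              x$system, length(x$values), 100 * x$fractions[1]))
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.ensemble_pca <- function(x, ...) {
  tibble(component = seq_along(x$values), eigenvalue = x$values,
         variance_fraction = x$fractions)
}

#' @exportS3Method broom::glance
glance.ensemble_pca <- function(x, ...) {
  tibble(n_modes = length(x$values), total_variance = sum(x$values),
         pc1_fraction = x$fractions[1], system = x$system)
}

#' Extreme projections along a principal component
#'
#' Locates the frames with minimal and maximal projection on the chosen
#' mode and reconstructs `n_interpolated` structures evenly spaced between
#' those extremes along the mode (mean + t * eigenvector). The result is an
#' ensemble whose endpoints are the extreme projected conformations
#' reconstructed on the mode; write it with [write_ensemble_pdb()].
#'
#' @param pca an `ensemble_pca`.
#' @param component mode index (default 1 = PC1).
#' @param n_interpolated number of structures (>= 2).
#' @return An [new_ensemble()] of interpolated structures, with attributes
#'   `min_frame`/`max_frame` (original frame indices of the extremes).
#' @export
extreme_projections <- function(pca, component = 1L, n_interpolated = 11L) {
  if (component > length(pca$values)) abort("component exceeds rank")
  if (pca$values[component] <= 0) abort("zero-variance component")
  if (n_interpolated < 2) abort("need at least 2 interpolated structures")
  proj <- pca$projections[, component]
  t_seq <- seq(min(proj), max(proj), length.out = n_interpolated)
  v <- pca$vectors[, component]
  n <- length(pca$residue_ids)
  coords <- array(NA_real_, c(n_interpolated, n, 3))
  for (i in seq_along(t_seq)) {
    coords[i, , ] <- pca$mean +
      matrix(t_seq[i] * v, n, 3, byrow = TRUE)
  }
  out <- new_ensemble(coords, pca$residue_ids,
                      system = paste0(pca$system, "-pc", component))
  attr(out, "min_frame") <- which.min(proj)
  attr(out, "max_frame") <- which.max(proj)
  attr(out, "projection_range") <- range(proj)
  out
}
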