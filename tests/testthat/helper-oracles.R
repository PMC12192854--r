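# Independent oracles and small fixtures used across the suite.

# --- brute-force betweenness ------------------------------------------------
# Exhaustive all-pairs shortest-path counting on a symmetric length matrix
# (Inf = no edge): Floyd-Warshall distances, then path counts sigma(s, t)
# accumulated in order of increasing distance from s, then pair-by-pair
# dependency sums. Normalized by (n-1)(n-2)/2.
betweenness_oracle <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  # SIG[s, v]: number of distinct shortest s->v paths, filled in order of
  # increasing distance from s
  SIG <- matrix(0, n, n)
  for (s in seq_len(n)) {
    SIG[s, s] <- 1
    for (v in order(D[s, ])) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(is.finite(L[, v]) &
                      abs(D[s, ] + L[, v] - D[s, v]) < 1e-9)
      SIG[s, v] <- sum(SIG[s, pred])
    }
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (abs(D[s, v] + D[v, t] - D[s, t]) < 1e-9)
          b[v] <- b[v] + SIG[s, v] * SIG[v, t] / SIG[s, t]
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# random connected weighted graph as a dccm-like matrix (entries in (0,1))
random_corr_graph <- function(n, p_edge = 0.45, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(0, n, n)
      ut <- which(upper.tri(A))
      on <- ut[stats::runif(length(ut)) < p_edge]
      A[on] <- stats::runif(length(on), 0.81, 0.99)
      A <- A + t(A)
      diag(A) <- 1
      g <- igraph::graph_from_adjacency_matrix(A > 0.8, mode = "undirected",
                                               diag = FALSE)
      if (igraph::is_connected(g) && igraph::ecount(g) >= n) break
    }
    A
  })
}

as_dccm <- function(M, ids = seq_len(nrow(M))) {
  dimnames(M) <- list(ids, ids)
  attr(M, "residue_ids") <- as.integer(ids)
  attr(M, "system") <- "toy"
  class(M) <- c("dccm_matrix", class(M))
  M
}

# --- Wilcoxon signed-rank enumeration --------------------------------------
# exact two-sided p for the signed-rank statistic by enumerating all 2^n
# sign assignments (no ties, no zeros)
signed_rank_enum <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  list(statistic = v_obs, p = min(1, 2 * min(p_low, p_high)))
}

# --- geometry fixtures ------------------------------------------------------
# ensemble with F frames all equal to the given coordinate matrix
static_ensemble <- function(xyz, n_frames = 4, ...) {
  coords <- array(NA_real_, c(n_frames, nrow(xyz), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- xyz
  new_ensemble(coords, seq_len(nrow(xyz)), ...)
}

ensemble_from_frames <- function(frames, ...) {
  coords <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  new_ensemble(coords, seq_len(nrow(frames[[1]])), ...)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# analytic SASA of a probe-inflated sphere partially buried by one neighbor
two_sphere_exposed <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# tiny structure: n carbon atoms, one per residue
carbon_structure <- function(xyz, residue_id = seq_len(nrow(xyz))) {
  structure_model(tibble::tibble(
    atom_name = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    residue_id = residue_id, residue_name = "ALA", chain_id = "A"))
}
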