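test_that("DCCM matches hand computation on a tiny ensemble", {
  # 3 residues, 4 frames; residue 2 moves identically to residue 1,
  # residue 3 mirrors residue 1 exactly
  base <- reference_curve(3)
  disp <- c(0.5, -0.5, 1.0, -1.0)
  frames <- lapply(disp, function(t) {
    m <- base
    m[1, 1] <- m[1, 1] + t
    m[2, 1] <- m[2, 1] + t
    m[3, 1] <- m[3, 1] - t
    m
  })
  ens <- ensemble_from_frames(frames, aligned = TRUE)
  C <- dccm(ens)
  expect_equal(unname(C[1, 2]), 1, tolerance = 1e-10)
  expect_equal(unname(C[1, 3]), -1, tolerance = 1e-10)

  # full hand computation on arbitrary displacements
  withr::with_seed(8, {
    frames2 <- lapply(1:4, function(i) base + matrix(rnorm(9), 3, 3))
  })
  ens2 <- ensemble_from_frames(frames2, aligned = TRUE)
  C2 <- dccm(ens2)
  X <- array(unlist(frames2), c(3, 3, 4))
  manual <- matrix(0, 3, 3)
  dots <- matrix(0, 3, 3)
  mu <- apply(X, c(1, 2), mean)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (f in 1:4) s <- s + sum((X[i, , f] - mu[i, ]) * (X[j, , f] - mu[j, ]))
    dots[i, j] <- s
  }
  for (i in 1:3) for (j in 1:3)
    manual[i, j] <- dots[i, j] / sqrt(dots[i, i] * dots[j, j])
  expect_equal(unclass(C2), manual, tolerance = 1e-10, ignore_attr = TRUE)

  # invariants: symmetry, unit diagonal, bounds
  expect_equal(unclass(C2), t(unclass(C2)))
  expect_equal(unname(diag(C2)), rep(1, 3))
  expect_true(all(abs(C2) <= 1))
})

test_that("DCCM agrees with the reference implementation on aligned data", {
  e <- sample_ensemble(
    build_planted_covariance(synthetic_domain_map(),
                             coupling_spec(0.8, integer(0), 0.5, 0.1)),
    reference_curve(40), 100, seed = 6)
  ours <- dccm(e)
  xyz <- t(apply(e$coords, 1, function(m) as.vector(t(m))))
  theirs <- bio3d::dccm(xyz)
  expect_equal(unclass(ours), unclass(theirs), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("zero-variance residues are flagged and zeroed", {
  base <- reference_curve(4)
  frames <- lapply(c(-1, 0, 1), function(t) {
    m <- base; m[1:3, ] <- m[1:3, ] + t; m
  })
  ens <- ensemble_from_frames(frames, aligned = TRUE)
  expect_warning(C <- dccm(ens), "zero-variance")
  expect_equal(unname(C[4, 1:3]), rep(0, 3))
  expect_equal(unname(C[4, 4]), 1)
})

test_that("DCCM similarity reduces to flattened-vector correlation", {
  A <- as_dccm(random_corr_graph(10, seed = 1))
  expect_equal(dccm_similarity(A, A)$r, 1, tolerance = 1e-12)

  B <- -unclass(A); diag(B) <- 1
  expect_equal(dccm_similarity(A, as_dccm(B))$r, -1, tolerance = 1e-12)

  B2 <- as_dccm(random_corr_graph(10, seed = 2))
  got <- dccm_similarity(A, B2)
  ut <- upper.tri(A)
  expect_equal(got$r, cor(unclass(A)[ut], unclass(B2)[ut]), tolerance = 1e-12)
  expect_equal(got$p_value,
               cor.test(unclass(A)[ut], unclass(B2)[ut])$p.value,
               tolerance = 1e-12)

  K <- as_dccm(matrix(1, 4, 4))
  expect_error(dccm_similarity(K, K), "constant")
})

test_that("graph construction applies the strict |c| > threshold rule", {
  I <- as_dccm(diag(10))
  g0 <- build_graph(I, 0.8)
  expect_equal(igraph::ecount(g0$graph), 0)

  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 0.8        # exactly at threshold: no edge
  M[1, 3] <- M[3, 1] <- 0.80001    # just above: edge
  g <- build_graph(as_dccm(M), 0.8)
  expect_equal(igraph::ecount(g$graph), 1)
  expect_equal(g$node_residues, c(1L, 3L))

  expect_error(build_graph(as_dccm(M), 1.2), "threshold")

  # planted block: edge count equals brute-force pair enumeration
  C <- build_planted_covariance(synthetic_domain_map(),
                                coupling_spec(0.85, integer(0), 0.5, 0.1))
  e <- sample_ensemble(C, reference_curve(40), 800, seed = 13)
  d <- dccm(e)
  gg <- build_graph(d, 0.8)
  expect_equal(igraph::ecount(gg$graph),
               sum(abs(unclass(d)[upper.tri(d)]) > 0.8))

  # edge set monotone non-increasing in the threshold
  counts <- vapply(c(0.7, 0.75, 0.8, 0.85, 0.9), function(th)
    igraph::ecount(build_graph(d, th)$graph), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Louvain communities recover cliques with correct purity", {
  M <- diag(10)
  M[1:5, 1:5] <- 0.9; M[6:10, 6:10] <- 0.9; diag(M) <- 1
  dm <- domain_map(list(SH3 = 1:5, SH2 = 6:10))
  g <- build_graph(as_dccm(M), 0.8)
  p <- detect_communities(g, dm, seed = 1)
  expect_equal(nrow(p$modules), 2)
  expect_equal(sort(p$modules$size), c(5, 5))
  expect_equal(p$modules$purity, c(1, 1))  # single-region cliques

  # forced mixed module: 2 SH3 + 1 SH2 + 1 SH1N residues in one clique
  M2 <- diag(4); M2[,] <- 0.9; diag(M2) <- 1
  dm2 <- domain_map(list(SH3 = 1:2, SH2 = 3, SH1N = 4))
  p2 <- detect_communities(build_graph(as_dccm(M2), 0.8), dm2, seed = 1)
  expect_equal(nrow(p2$modules), 1)
  expect_equal(p2$modules$purity, 0.5)
  expect_equal(p2$modules$dominant_region, "SH3")

  expect_error(detect_communities(build_graph(as_dccm(diag(5)), 0.8), dm),
               "empty graph")
})

test_that("isolated residues are recorded as unassigned", {
  M <- diag(6)
  M[1:4, 1:4] <- 0.9; diag(M) <- 1
  dm <- domain_map(list(SH3 = 1:4, SH2 = 5:6))
  p <- detect_communities(build_graph(as_dccm(M), 0.8), dm, seed = 1)
  expect_equal(p$unassigned, c(5L, 6L))
})

test_that("integration module selection follows purity and tie-break rules", {
  fake <- function(purities, sizes, ids = seq_along(purities)) {
    structure(list(modules = tibble::tibble(
      module = ids, size = sizes, purity = purities,
      dominant_region = "SH3"), min_module_size = 4L),
      class = "community_partition")
  }
  expect_equal(integration_module(fake(c(1.0, 0.9, 0.4), c(10, 10, 10))), 3)
  expect_equal(integration_module(fake(c(0.5, 0.5), c(6, 10))), 2)  # larger
  expect_equal(integration_module(fake(c(0.5, 0.5), c(8, 8))), 1)   # lower id
  expect_equal(integration_module(fake(c(0.2, 0.5), c(3, 8))), 2)   # size gate
  expect_error(integration_module(fake(c(0.2), c(2))), "eligible")
})

test_that("betweenness matches structure on paths, stars and the brute-force oracle", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 0.9
  path3[2, 3] <- path3[3, 2] <- 0.9
  diag(path3) <- 1
  b <- betweenness_profile(build_graph(as_dccm(path3), 0.8))
  expect_equal(b$betweenness, c(0, 1, 0))

  star <- diag(5)
  star[1, 2:5] <- star[2:5, 1] <- 0.9; diag(star) <- 1
  bs <- betweenness_profile(build_graph(as_dccm(star), 0.8))
  expect_equal(which.max(bs$betweenness), 1)
  expect_true(all(bs$betweenness[2:5] == 0))

  for (seed in 1:5) {
    n <- sample(6:10, 1)
    M <- random_corr_graph(n, seed = seed * 17)
    g <- build_graph(as_dccm(M), 0.8)
    got <- betweenness_profile(g)
    L <- -log(abs(M)); L[abs(M) <= 0.8] <- Inf; diag(L) <- Inf
    expect_equal(got$betweenness, betweenness_oracle(L), tolerance = 1e-10)
  }
})

test_that("top connectors and threshold consistency follow their definitions", {
  prof <- tibble::tibble(residue_id = 1:6,
                         betweenness = c(0.5, 0.9, 0.9, 0.1, 0, 0))
  expect_equal(top_connectors(prof, 3), c(2L, 3L, 1L))  # ties by residue id

  M <- diag(6)
  M[1, 2] <- M[2, 1] <- 0.95
  M[2, 3] <- M[3, 2] <- 0.95
  M[3, 4] <- M[4, 3] <- 0.95
  diag(M) <- 1
  cons <- threshold_consistency(as_dccm(M), thresholds = c(0.7, 0.8, 0.9), n = 2)
  # residues 2 and 3 carry all shortest paths at every threshold
  expect_equal(cons$consistency[cons$residue_id %in% c(2, 3)], c(1, 1))
  expect_equal(cons$consistency[cons$residue_id %in% c(5, 6)], c(0, 0))
  expect_warning(
    threshold_consistency(as_dccm(M), thresholds = c(0.8, 0.96), n = 2),
    "empty graph")
  suppressWarnings(
    expect_error(threshold_consistency(as_dccm(diag(4)), thresholds = c(0.8)),
                 "all thresholds"))
})
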