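map40 <- synthetic_domain_map()

test_that("planted covariance matches the block/hub template and is PSD", {
  # two regions, no hubs, zero baseline: exact block-diagonal correlation
  dm <- domain_map(list(SH3 = 1:4, SH2 = 5:8))
  sp <- coupling_spec(0.7, integer(0), 0.5, 0)
  C <- build_planted_covariance(dm, sp)
  expect_equal(unname(C[1:4, 5:8]), matrix(0, 4, 4))
  expect_equal(unname(C[2, 3]), 0.7)
  expect_equal(unname(diag(C)), rep(1, 8))

  # hub residue h: cross-region entries set to rho_hub by construction
  sp2 <- coupling_spec(0.7, 2L, 0.5, 0.1)
  C2 <- build_planted_covariance(dm, sp2)
  expect_equal(unname(C2["2", as.character(5:8)]), rep(0.5, 4))
  expect_equal(unname(C2["2", "3"]), 0.7)

  # independent eigensolver oracle: minimum eigenvalue >= 0 after repair
  dm10 <- domain_map(list(SH3 = 1:3, SH2 = 4:6, SH1N = 7:10))
  C3 <- build_planted_covariance(dm10, coupling_spec(0.85, c(2L, 8L), 0.85, 0.1))
  ev <- eigen(unclass(C3), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(unname(diag(C3)), rep(1, 10))
})

test_that("coupling specs reject inconsistent correlation orderings", {
  expect_error(coupling_spec(0.5, 1L, 0.8, 0.1), "hub_cross_corr <= intra")
  expect_error(coupling_spec(0.8, 1L, 0.5, 0.6), "baseline_corr < hub")
})

test_that("the ensemble sampler is seed-deterministic and matches its target", {
  ref <- reference_curve(40)
  C <- build_planted_covariance(map40, coupling_spec(0.8, integer(0), 0.5, 0.1))
  a <- sample_ensemble(C, ref, 50, seed = 11)
  b <- sample_ensemble(C, ref, 50, seed = 11)
  expect_identical(a$coords, b$coords)
  expect_true(a$aligned)
  expect_error(sample_ensemble(C, ref, 1, seed = 1), ">= 2")

  # identity correlation: sampled DCCM off-diagonals within ~2/sqrt(F) of 0
  I40 <- diag(40); dimnames(I40) <- list(1:40, 1:40)
  e <- sample_ensemble(I40, ref, 1e4, seed = 2)
  d <- dccm(e)
  off <- abs(unclass(d)[upper.tri(d)])
  expect_lt(max(off), 0.05)

  # planted 0.8 block: mean sampled intra-block correlation within 0.05
  e2 <- sample_ensemble(C, ref, 5e3, seed = 3)
  d2 <- dccm(e2)
  intra <- unclass(d2)[1:10, 1:10][upper.tri(diag(10))]
  expect_lt(abs(mean(intra) - 0.8), 0.05)
})

test_that("sampled DCCMs converge to the planted matrix within the noise envelope", {
  ref <- reference_curve(40)
  C <- build_planted_covariance(map40, coupling_spec(0.85, 5L, 0.6, 0.1))
  e <- sample_ensemble(C, ref, 1e4, seed = 5)
  d <- dccm(e)
  dev <- abs(unclass(d) - unclass(C))
  envelope <- 3 / sqrt(1e4) * (1 - unclass(C)^2)
  frac_violating <- mean((dev > envelope)[upper.tri(C)])
  expect_lt(frac_violating, 0.01)
})

test_that("study sets echo their configuration and plant class-dependent hubs", {
  study <- generate_study_set(list(n_frames = 120L), seed = 42)
  man <- study$manifest
  expect_equal(nrow(man), 6)
  expect_equal(sum(man$label == 1), 2)
  expect_equal(sum(man$label == 0), 4)
  expect_length(allonet:::manifest_ensembles(man, 1), 3)
  expect_error(generate_study_set(list(labels = c(1L, 1L))), "inactive")

  # distinct per-system seeds: ensembles differ
  e1 <- allonet:::manifest_ensembles(man, 1)[[1]]
  e2 <- allonet:::manifest_ensembles(man, 3)[[1]]
  expect_false(identical(e1$coords, e2$coords))

  # hub-row mean correlation higher in active than inactive, recomputed
  # from the sampled ensembles
  d_act <- dccm(e1)
  d_inact <- dccm(e2)
  h <- as.character(study$hub_residues[1])
  others <- setdiff(colnames(d_act), h)
  expect_gt(mean(unclass(d_act)[h, others]), mean(unclass(d_inact)[h, others]) + 0.1)
})

test_that("backbone covariance keeps hub couplings above the edge threshold", {
  C <- build_backbone_covariance(map40, c(5L, 15L, 25L, 35L))
  ev <- eigen(unclass(C), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_gt(C["5", "15"], 0.8)   # hub-hub clique edge
  expect_gt(C["5", "4"], 0.8)    # hub-anchor edge
  expect_gt(C["2", "3"], 0.8)    # intra-block edge
  expect_lt(C["5", "7"], 0.8)    # hub to own-block non-anchor: no edge
  expect_lt(C["3", "13"], 0.8)   # cross-block baseline: no edge
})

test_that("feature tables are reproducible with planted separation structure", {
  a <- generate_feature_table(100, effect_size = 2, seed = 9)
  b <- generate_feature_table(100, effect_size = 2, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 200)
  expect_equal(sum(a$label), 100)
  expect_length(attr(a, "informative"), 7)

  # imbalanced classes via a length-2 frame count
  im <- generate_feature_table(c(40, 160), effect_size = 1, seed = 1)
  expect_equal(sum(im$label == 1), 40)

  # planted separation appears on informative features only
  big <- generate_feature_table(2000, effect_size = 3, n_informative = 2, seed = 3)
  d_inf <- mean(big$feature_01[big$label == 1]) - mean(big$feature_01[big$label == 0])
  d_noise <- mean(big$feature_10[big$label == 1]) - mean(big$feature_10[big$label == 0])
  expect_equal(d_inf, 3, tolerance = 0.1)
  expect_lt(abs(d_noise), 0.15)
  expect_error(generate_feature_table(10, effect_size = -1), ">= 0")
})
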