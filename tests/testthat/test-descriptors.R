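test_that("Kabsch superposition recovers rigid transformations exactly", {
  xyz <- reference_curve(6)
  s <- superpose(xyz, xyz)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)

  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 degrees about z
  moved <- xyz %*% R + matrix(c(3, -2, 7), 6, 3, byrow = TRUE)
  s2 <- superpose(moved, xyz)
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(s2$coords, xyz, tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(superpose(xyz[1:2, ], xyz[1:2, ]), "at least 3")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(superpose(line, line), "collinear")
})

test_that("fitted RMSD is optimal against random rotations", {
  withr::with_seed(7, {
    for (rep in 1:3) {
      a <- matrix(rnorm(18, sd = 3), 6, 3)
      b <- matrix(rnorm(18, sd = 3), 6, 3)
      best <- superpose(a, b)$rmsd
      bc <- sweep(b, 2, colMeans(b))
      ac <- sweep(a, 2, colMeans(a))
      brute <- min(vapply(1:2000, function(i) {
        sqrt(mean(rowSums((ac %*% random_rotation() - bc)^2)))
      }, numeric(1)))
      expect_lte(best, brute + 1e-12)
    }
  })
})

test_that("RMSD series follow the fit conventions and hand calculations", {
  ref <- reference_curve(5)
  ens <- static_ensemble(ref, n_frames = 3)
  expect_equal(rmsd_series(ens)$rmsd, rep(0, 3), tolerance = 1e-10)

  # translated frame: zero after fitting
  ens2 <- ens
  ens2$coords[2, , ] <- ens2$coords[2, , ] + 5
  expect_equal(rmsd_series(ens2)$rmsd[2], 0, tolerance = 1e-10)

  # hand-computed two-frame toy: fit is identity (centroid-preserving,
  # symmetric displacement), rmsd = sqrt(mean d^2)
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0.5, 0.5, 1))
  shifted <- base
  shifted[1, 3] <- 0.3
  shifted[2, 3] <- -0.3
  ens3 <- ensemble_from_frames(list(base, shifted))
  out <- rmsd_series(ens3, reference = base)
  fitted <- superpose(shifted, base)$coords
  expect_equal(out$rmsd[2], sqrt(mean(rowSums((fitted - base)^2))),
               tolerance = 1e-12)

  dm <- domain_map(list(SH3 = 1:3, SH2 = 4:5))
  per_dom <- rmsd_series(ens3, domain = "SH3", map = dm)
  expect_equal(nrow(per_dom), 2)
  expect_error(rmsd_series(ens3, domain = "SH1N", map = dm), "unknown domain")
})

test_that("RMSF profiles recover static and planted-variance structure", {
  ref <- reference_curve(8)
  expect_equal(rmsf_profile(static_ensemble(ref))$rmsf, rep(0, 8),
               tolerance = 1e-10)

  # planted high-variance residue (sd x3) dominates the profile
  S <- diag(c(1, 1, 1, 9, 1, 1, 1, 1)); dimnames(S) <- list(1:8, 1:8)
  e <- sample_ensemble(S, ref, 4000, seed = 4)
  prof <- rmsf_profile(e)
  expect_equal(which.max(prof$rmsf), 4)
  # rmsf^2 converges to the planted 3-axis variance sum (3 * 9)
  expect_equal(prof$rmsf[4]^2, 27, tolerance = 0.05)

  d <- delta_rmsf(prof, prof)
  expect_equal(d$delta_rmsf, rep(0, 8))
  expect_error(delta_rmsf(prof, prof[1:4, ]), "aligned")
})

test_that("geometry descriptors match hand-computed values", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(0, 2, 0))
  ens <- static_ensemble(xyz, n_frames = 3)
  spec <- list(feat_distance("d12", 1, 2),
               feat_angle("a123", 1, 2, 3),
               feat_centroid_distance("c", "SH3", "SH2"))
  dm <- domain_map(list(SH3 = 1:2, SH2 = 3:4))
  g <- geometry_series(ens, spec, dm)
  expect_equal(g$d12, rep(3.8, 3))
  expect_equal(g$a123, rep(180, 3))                    # collinear triplet
  cent_a <- colMeans(xyz[1:2, ]); cent_b <- colMeans(xyz[3:4, ])
  expect_equal(g$c, rep(sqrt(sum((cent_a - cent_b)^2)), 3))
  expect_error(geometry_series(ens, list(feat_distance("x", 1, 99))),
               "not in selection")
})

test_that("representative structures recover planted conformer mixtures", {
  withr::with_seed(21, {
    conf_a <- reference_curve(6)
    conf_b <- conf_a + matrix(c(10, 0, 0), 6, 3, byrow = TRUE) +
      matrix(rnorm(18, sd = 0.2), 6, 3)
    frames <- c(
      lapply(1:6, function(i) conf_a + matrix(rnorm(18, sd = 0.1), 6, 3)),
      lapply(1:4, function(i) conf_b + matrix(rnorm(18, sd = 0.1), 6, 3)))
    ens <- ensemble_from_frames(frames)
    rep_str <- representative_structure(ens, k_candidates = 2:4)
    expect_lte(rep_str$frame, 6)   # medoid from the 60% cluster
    expect_equal(max(rep_str$cluster_sizes), 6)
  })
})

test_that("degenerate and brute-force medoid cases behave as documented", {
  ens <- static_ensemble(reference_curve(5), n_frames = 6)
  expect_warning(res <- representative_structure(ens), "degenerate")
  expect_equal(res$frame, 1L)

  # 4 crafted frames, k = 2 (shape changes, not rigid motions): medoid of
  # the most populated cluster equals the brute-force minimizer over all
  # medoid pairs
  base <- reference_curve(5)
  bend <- function(m, delta) { m[1, ] <- m[1, ] + delta; m }
  frames <- list(base,
                 bend(base, c(0.4, 0, 0)),
                 bend(base, c(0.2, 0.3, 0)),
                 bend(base, c(8, -5, 3)))
  ens4 <- ensemble_from_frames(frames)
  got <- representative_structure(ens4, k_candidates = 2)
  D <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4)
    D[i, j] <- D[j, i] <- superpose(frames[[j]], frames[[i]])$rmsd
  combos <- utils::combn(4, 2, simplify = FALSE)
  costs <- vapply(combos, function(m) {
    sum(pmin(D[, m[1]], D[, m[2]]))
  }, numeric(1))
  best <- combos[[which.min(costs)]]
  assign_to <- apply(D[, best], 1, which.min)
  big <- best[which.max(tabulate(assign_to))]
  expect_equal(got$frame, big)
})

test_that("distribution comparisons use the right Wilcoxon flavor", {
  expect_error(compare_distributions(1:5, 1:5, paired = TRUE), "degenerate")

  withr::with_seed(3, {
    a <- rnorm(50); b <- rnorm(50) + 5
    res <- compare_distributions(a, b)
    expect_lt(res$p_value, 0.001)
    expect_match(res$method, "rank-sum")
  })

  # n = 6 paired toy versus exhaustive sign-enumeration oracle
  d <- c(1.3, -0.4, 2.2, 0.8, -1.7, 0.6)
  a <- seq(10, 15); b <- a - d
  res <- compare_distributions(a, b, paired = TRUE)
  oracle <- signed_rank_enum(d)
  expect_equal(unname(res$statistic), oracle$statistic)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_match(res$method, "signed-rank")
})
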