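test_that("single-atom and well-separated SASA match the analytic sphere", {
  st <- carbon_structure(rbind(c(0, 0, 0)))
  res <- sasa(st)
  expect_equal(res$total, 4 * pi * 3.1^2, tolerance = 0.01)

  two <- carbon_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  res2 <- sasa(two)
  expect_equal(res2$total, 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(res2$residue$sasa, res2$atom$sasa)  # one atom per residue

  missing <- structure_model(tibble::tibble(
    atom_name = "X", element = "Zz", x = 0, y = 0, z = 0,
    residue_id = 1L, residue_name = "UNK", chain_id = "A"))
  expect_error(sasa(missing), "no radius")
})

test_that("two overlapping spheres match the closed-form buried-cap area", {
  d <- 2.0
  st <- carbon_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
  res <- sasa(st)
  R <- 1.7 + 1.4
  analytic <- two_sphere_exposed(R, R, d)
  expect_equal(res$atom$sasa[1], analytic, tolerance = 0.02)
  expect_equal(res$atom$sasa[2], analytic, tolerance = 0.02)
})

test_that("SASA converges in the number of sphere points", {
  st <- reference_structure(20)
  a <- sasa(st, n_points = 960)
  b <- sasa(st, n_points = 3840)
  expect_lt(abs(a$total - b$total) / b$total, 0.02)
})

test_that("interface detection matches brute-force delta-SASA recomputation", {
  # two synthetic helices packed side by side ~5 A apart
  h1 <- reference_curve(12)
  h2 <- sweep(reference_curve(12), 2, c(0, 0, 50), "+")  # far: no interface
  st_far <- carbon_structure(rbind(h1, h2), residue_id = 1:24)
  far <- interface_residues(st_far, 1:12, 13:24)
  expect_length(attr(far, "interface"), 0)

  withr::with_seed(5, {
    straight <- function(n, offset) cbind(
      seq(0, by = 3.8, length.out = n) + rnorm(n, sd = 0.05),
      rep(offset, n), rnorm(n, sd = 0.05))
    packed <- carbon_structure(rbind(straight(10, 0), straight(10, 5)),
                               residue_id = 1:20)
  })
  res <- interface_residues(packed, 1:10, 11:20)
  expect_gt(length(attr(res, "interface")), 10)  # contact-facing residues

  # brute-force per-residue recomputation
  s_a <- sasa(packed[packed$residue_id %in% 1:10, ])$residue
  s_c <- sasa(packed)$residue
  for (r in 1:10) {
    d_brute <- s_a$sasa[s_a$residue_id == r] - s_c$sasa[s_c$residue_id == r]
    expect_equal(res$delta_sasa[res$residue_id == r], d_brute,
                 tolerance = 1e-10)
  }

  # delta-SASA is non-negative up to point-sampling noise
  expect_gte(min(res$delta_sasa), -0.5)

  # symmetric in the partition order; huge threshold empties the set
  swapped <- interface_residues(packed, 11:20, 1:10)
  expect_equal(sort(attr(swapped, "interface")), sort(attr(res, "interface")))
  expect_length(attr(interface_residues(packed, 1:10, 11:20, threshold = Inf),
                     "interface"), 0)
  expect_error(interface_residues(packed, integer(0), 1:10), "non-empty")
})

test_that("interdomain interface sets union all region pairs", {
  st <- reference_structure(40)
  map <- synthetic_domain_map()
  res <- interdomain_interfaces(st, map, n_points = 480)
  expect_true(all(c("pair", "residue_id", "delta_sasa") %in% names(res)))
  iface <- attr(res, "interface")
  expect_gt(length(iface), 0)
  # region-boundary residues on the curve are interfacial
  expect_true(10 %in% iface || 11 %in% iface)
})

test_that("pocket surface area follows the residue-selection oracle", {
  st <- reference_structure(12)
  far_ligand <- matrix(c(500, 0, 0), 1, 3)
  expect_warning(area0 <- pocket_surface_area(st, far_ligand), "no residue")
  expect_equal(as.numeric(area0), 0)
  expect_warning(
    expect_warning(pocket_surface_area(st, rbind(c(0, 0, 0)), radius = 0),
                   "non-positive"),
    "no residue")

  lig <- matrix(colMeans(cbind(st$x, st$y, st$z)[3:5, ]), 1, 3)
  area <- pocket_surface_area(st, lig, radius = 5)
  pocket <- attr(area, "pocket_residues")
  # brute-force residue selection
  xyz <- cbind(st$x, st$y, st$z)
  d <- sqrt(colSums((t(xyz) - as.vector(lig))^2))
  expect_equal(pocket, sort(unique(st$residue_id[d <= 5])))
  # area equals the full-structure per-residue SASA summed over the pocket
  res_sasa <- sasa(st)$residue
  expect_equal(as.numeric(area),
               sum(res_sasa$sasa[res_sasa$residue_id %in% pocket]),
               tolerance = 1e-10)
  # occluding with the ligand shrinks the pocket surface
  area_lig <- pocket_surface_area(st, as.data.frame(lig) |>
                                    setNames(c("x", "y", "z")),
                                  radius = 5, include_ligand = TRUE)
  expect_lt(as.numeric(area_lig), as.numeric(area))
})

test_that("ligand contact occupancy counts frames within the radius", {
  ref <- reference_curve(6)
  ens <- static_ensemble(ref, n_frames = 10)
  near <- matrix(ref[5, ], 1, 3)
  far <- matrix(ref[5, ] + 100, 1, 3)
  lig <- c(replicate(8, near, simplify = FALSE),
           replicate(2, far, simplify = FALSE))
  occ <- ligand_contact_occupancy(ens, lig, radius = 5)
  expect_equal(occ$occupancy[occ$residue_id == 5], 0.8)
  iso <- which(sqrt(rowSums(sweep(ref, 2, ref[5, ])^2)) > 105)
  expect_true(all(occ$occupancy[iso] == 0))
  expect_error(ligand_contact_occupancy(ens, lig[1:9], radius = 5),
               "frame count")
})
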