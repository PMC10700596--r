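# a conformer from bare coordinates, carbon chemistry throughout
conformer_coords_for_test <- function(conf) as.matrix(conf$atoms[, c("x", "y", "z")])

conformer_from_coords <- function(xyz, charges = 0, desolv = 0, id = "lig") {
  vp <- default_vdw_params()
  cc <- vp[vp$element == "C", ]
  n <- nrow(xyz)
  ligand_conformer(data.frame(
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charges, n), desolv = rep_len(desolv, n),
    sqrtA = sqrt(cc$A), sqrtB = sqrt(cc$B)), id = id)
}

test_that("a congruent triplet yields an exact superposition pose", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0))
  spheres <- generate_matching_spheres(
    rbind(c(10, 5, 2), c(12, 5, 2), c(10, 8, 2)), dedup_radius = 0.01)
  lig <- conformer_from_coords(tri)
  poses <- orient_ligand(lig, spheres, distance_tol = 0.01)
  expect_gt(length(poses), 0)
  rmsds <- vapply(poses, function(p) {
    sqrt(mean(rowSums((p$coords[p$atom_triplet, ] -
                         spheres$centers[p$sphere_triplet, ])^2)))
  }, numeric(1))
  expect_lt(min(rmsds), 0.01)
  expect_true(all(vapply(poses, function(p) abs(det(p$R) - 1) < 1e-6,
                         logical(1))))
})

test_that("zero tolerance with incongruent distances yields no orientation", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0))
  spheres <- generate_matching_spheres(
    rbind(c(0, 0, 0), c(2.7, 0, 0), c(0, 3.9, 0)), dedup_radius = 0.01)
  lig <- conformer_from_coords(tri)
  expect_length(orient_ligand(lig, spheres, distance_tol = 0), 0)
})

test_that("triplet acceptance equals the exhaustive O(n^3 m^3) oracle", {
  set.seed(21)
  lig_xyz <- matrix(stats::rnorm(15, sd = 2), 5, 3)
  sph_xyz <- matrix(stats::rnorm(15, sd = 2), 5, 3)
  spheres <- generate_matching_spheres(sph_xyz, dedup_radius = 1e-6)
  lig <- conformer_from_coords(lig_xyz)
  tol <- 0.5
  poses <- orient_ligand(lig, spheres, distance_tol = tol,
                         max_orientations = 1e6)
  got <- unique(t(vapply(poses, function(p)
    c(p$atom_triplet, p$sphere_triplet), numeric(6))))
  # independent enumeration: unordered atom triplets x ordered sphere triplets
  dl <- as.matrix(dist(lig_xyz)); ds <- as.matrix(dist(spheres$centers))
  want <- list()
  for (a1 in 1:3) for (a2 in (a1 + 1):4) for (a3 in (a2 + 1):5)
    for (s1 in 1:5) for (s2 in 1:5) for (s3 in 1:5) {
      if (s1 == s2 || s1 == s3 || s2 == s3) next
      if (abs(dl[a1, a2] - ds[s1, s2]) <= tol &&
          abs(dl[a1, a3] - ds[s1, s3]) <= tol &&
          abs(dl[a2, a3] - ds[s2, s3]) <= tol)
        want[[length(want) + 1]] <- c(a1, a2, a3, s1, s2, s3)
    }
  want <- unique(do.call(rbind, want))
  expect_equal(nrow(got), nrow(want))
  expect_setequal(apply(got, 1, paste, collapse = ","),
                  apply(want, 1, paste, collapse = ","))
})

test_that("pose scoring terms vanish in their trivial limits and always sum", {
  tg <- cached_toy_grids()
  lig0 <- make_toy_ligand(tg$complex, net_charge = 0)
  poses <- orient_ligand(lig0, tg$grids$spheres, max_orientations = 5)
  sc <- score_pose(poses[[1]], lig0, tg$grids)
  expect_equal(sc$e_elec, 0)
  expect_equal(sc$e_total, sc$e_elec + sc$e_vdw + sc$e_desolv)
  expect_gte(sc$e_desolv, 0)
  # atoms in bulk solvent over the pocket mouth: zero occlusion, zero penalty
  far <- conformer_from_coords(rbind(c(0, 0, 10), c(1, 0, 10),
                                     c(0, 1, 10)), desolv = 2)
  pose <- structure(list(R = diag(3), t = c(0, 0, 0),
                         coords = conformer_coords_for_test(far)),
                    class = "pose")
  sc2 <- score_pose(pose, far, tg$grids)
  expect_equal(sc2$e_desolv, 0)
})

test_that("single-atom grid score matches the gridless pairwise oracle within 5 percent", {
  rec <- random_receptor(8, seed = 13, spread = 4)
  lat <- lattice_spec(c(-12, -12, -12), 0.3, c(81, 81, 81))
  dm <- assign_membrane_dielectric(rec, NULL, lat, eps_low = 4, eps_high = 4,
                                   surface_extension = 0)
  phi <- solve_potential_grid(rec, dm, tol = 1e-7)
  vg <- build_vdw_grid(rec, default_vdw_params(), lat)
  p <- c(6.1, 5.2, -4.3)  # well away from all atoms (uniform eps -> Coulomb)
  xyz <- as.matrix(rec[, c("x", "y", "z")])
  r <- sqrt(colSums((t(xyz) - p)^2))
  e_elec_direct <- sum(-0.5 * 332.063 * rec$charge / (4 * r))
  e_elec_grid <- -0.5 * interp_grid(phi, lat, matrix(p, 1))
  expect_lt(abs(e_elec_grid - e_elec_direct) / abs(e_elec_direct), 0.05)
  vp <- default_vdw_params()
  idx <- match(rec$element, vp$element)
  ccA <- sqrt(vp$A[vp$element == "C"]); ccB <- sqrt(vp$B[vp$element == "C"])
  e_vdw_direct <- ccA * sum(sqrt(vp$A[idx]) / pmax(r, 0.8)^12) -
    ccB * sum(sqrt(vp$B[idx]) / pmax(r, 0.8)^6)
  e_vdw_grid <- ccA * interp_grid(vg$vdw_a, lat, matrix(p, 1)) -
    ccB * interp_grid(vg$vdw_b, lat, matrix(p, 1))
  expect_lt(abs(e_vdw_grid - e_vdw_direct) / max(abs(e_vdw_direct), 1e-6),
            0.05)
})

test_that("atoms outside the box raise an explicit error", {
  tg <- cached_toy_grids()
  lig <- conformer_from_coords(rbind(c(50, 0, 0), c(51, 0, 0), c(50, 1, 0)))
  pose <- structure(list(R = diag(3), t = c(0, 0, 0),
                         coords = conformer_coords_for_test(lig)),
                    class = "pose")
  expect_error(score_pose(pose, lig, tg$grids), "outside")
})

test_that("dock_molecule returns the exhaustive minimum, idempotent under duplication", {
  tg <- cached_toy_grids()
  lig <- make_toy_ligand(tg$complex, net_charge = -1)
  res <- dock_molecule(list(lig), tg$grids, distance_tol = 0.4,
                       max_orientations = 60)
  expect_true(res$placed)
  # exhaustive oracle over the same enumeration
  poses <- orient_ligand(lig, tg$grids$spheres, distance_tol = 0.4,
                         max_orientations = 60)
  scores <- vapply(poses, function(p) {
    s <- try(score_pose(p, lig, tg$grids), silent = TRUE)
    if (inherits(s, "try-error")) Inf else s$e_total
  }, numeric(1))
  expect_equal(res$score$e_total, min(scores))
  res2 <- dock_molecule(list(lig, lig), tg$grids, distance_tol = 0.4,
                        max_orientations = 60)
  expect_equal(res2$score$e_total, res$score$e_total)
  # unplaceable ligand -> sentinel
  huge <- conformer_from_coords(rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0)))
  expect_false(dock_molecule(list(huge), tg$grids)$placed)
})

test_that("library ranking is ascending, stable, flags unplaced last, permutation-invariant", {
  tg <- cached_toy_grids()
  lib <- list(
    anion = list(make_toy_ligand(tg$complex, net_charge = -1)),
    cation = list(make_toy_ligand(tg$complex, net_charge = +1)),
    neutral = list(make_toy_ligand(tg$complex, net_charge = 0)),
    stranded = list(conformer_from_coords(
      rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0))))
  )
  rk <- rank_library(lib, tg$grids, distance_tol = 0.4,
                     max_orientations = 40)
  expect_equal(rk$id[1], "anion")
  expect_false(rk$placed[nrow(rk)])
  expect_equal(rk$id[nrow(rk)], "stranded")
  placed <- rk[rk$placed, ]
  expect_true(!is.unsorted(placed$e_total))
  rk2 <- rank_library(rev(lib), tg$grids, distance_tol = 0.4,
                      max_orientations = 40)
  expect_equal(rk2$id[rk2$placed], rk$id[rk$placed])
  expect_error(rank_library(list(), tg$grids), "non-empty")
})

test_that("a pocket-complementary anion outscores its charge-inverted twin", {
  tg <- cached_toy_grids()
  res_m <- dock_molecule(list(make_toy_ligand(tg$complex, -1)), tg$grids,
                         distance_tol = 0.4, max_orientations = 60)
  res_p <- dock_molecule(list(make_toy_ligand(tg$complex, +1)), tg$grids,
                         distance_tol = 0.4, max_orientations = 60)
  expect_lt(res_m$score$e_total, res_p$score$e_total)
})

test_that("docking scores are invariant under a rigid frame transform", {
  tc <- make_toy_complex(40, 15, seed = 9)
  lat <- lattice_spec(c(-11, -11, -11), 0.6, c(38, 38, 38))
  g1 <- build_scoring_grids(tc$receptor, tc$lipid_atoms,
                            tc$reference_ligand_atoms, lattice = lat,
                            tol = 1e-6)
  lig <- make_toy_ligand(tc, net_charge = -1)
  r1 <- dock_molecule(list(lig), g1, distance_tol = 0.4,
                      max_orientations = 50)
  # rotate everything 90 degrees about z and translate; the lattice frame
  # transforms with the system, so all relative geometry is unchanged
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  shift <- c(5, -3, 2)
  tf <- function(m) sweep(as.matrix(m) %*% t(Rz), 2, -shift)
  rec2 <- tc$receptor
  rec2[, c("x", "y", "z")] <- tf(rec2[, c("x", "y", "z")])
  rec2 <- receptor_model(rec2)
  # rotating the axis-aligned box 90 deg about z maps x' = -y, y' = x
  lat2 <- lattice_spec(
    c(-(lat$origin[2] + (lat$dims[2] - 1) * lat$spacing),
      lat$origin[1], lat$origin[3]) + shift,
    lat$spacing, c(lat$dims[2], lat$dims[1], lat$dims[3]))
  g2 <- build_scoring_grids(rec2, tf(tc$lipid_atoms),
                            tf(tc$reference_ligand_atoms), lattice = lat2,
                            tol = 1e-6)
  lig2_atoms <- lig$atoms
  lig2_atoms[, c("x", "y", "z")] <- tf(lig2_atoms[, c("x", "y", "z")])
  lig2 <- ligand_conformer(lig2_atoms, lig$bonds, id = lig$id)
  r2 <- dock_molecule(list(lig2), g2, distance_tol = 0.4,
                      max_orientations = 50)
  expect_equal(r2$score$e_total, r1$score$e_total, tolerance = 1e-5)
})
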