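test_that("dielectric classification honours the inflated-sphere threshold geometry", {
  rec <- single_atom_receptor("C", charge = 0, radius = 1.5)
  lat <- lattice_spec(c(-6, -6, -6), 0.1, c(121, 121, 121))
  dm <- assign_membrane_dielectric(rec, NULL, lat, surface_extension = 1.9)
  at <- function(x) dm$lattice[round((x + 6) / 0.1) + 1, 61, 61]
  expect_equal(at(3.3), 2)   # 1.5 + 1.9 = 3.4: inside
  expect_equal(at(3.5), 78)  # outside
})

test_that("lipid atoms beyond the 17 A ring cutoff contribute no low-dielectric volume", {
  rec <- single_atom_receptor("C", charge = 0, radius = 1.5)
  lat <- lattice_spec(c(-25, -6, -6), 0.5, c(61, 25, 25))
  far <- matrix(c(-20, 0, 0), 1)  # 20 A from the only receptor atom
  dm_far <- assign_membrane_dielectric(rec, far, lat)
  dm_none <- assign_membrane_dielectric(rec, NULL, lat)
  expect_identical(dm_far$lattice, dm_none$lattice)
  expect_equal(nrow(dm_far$lipid_atoms), 0)
  near <- matrix(c(-10, 0, 0), 1)
  dm_near <- assign_membrane_dielectric(rec, near, lat)
  expect_gt(sum(dm_near$lattice == 2), sum(dm_none$lattice == 2))
})

test_that("dielectric map equals the all-pairs distance oracle on a random fixture", {
  rec <- random_receptor(30, seed = 11)
  lat <- lattice_around(rec, spacing = 1.0, margin = 5)
  set.seed(4)
  lip <- cbind(stats::runif(20, -25, 25), stats::runif(20, -25, 25),
               stats::runif(20, -25, 25))
  dm <- assign_membrane_dielectric(rec, lip, lat)
  xyz <- as.matrix(rec[, c("x", "y", "z")])
  keep <- apply(lip, 1, function(p)
    min(sqrt(colSums((t(xyz) - p)^2))) <= 17)
  lipk <- lip[keep, , drop = FALSE]
  ax <- lapply(1:3, function(k)
    lat$origin[k] + lat$spacing * (seq_len(lat$dims[k]) - 1))
  oracle <- array(78, dim = lat$dims)
  for (i in seq_len(lat$dims[1])) for (j in seq_len(lat$dims[2]))
    for (k in seq_len(lat$dims[3])) {
      p <- c(ax[[1]][i], ax[[2]][j], ax[[3]][k])
      inside <- any(sqrt(colSums((t(xyz) - p)^2)) <= rec$radius + 1.9)
      if (!inside && nrow(lipk))
        inside <- any(sqrt(colSums((t(lipk) - p)^2)) <= 1.7)
      if (inside) oracle[i, j, k] <- 2
    }
  expect_identical(dm$lattice, oracle)
})

test_that("polar charge perturbation shifts the pair and conserves residue charge", {
  rec <- make_toy_complex(50, 15, seed = 1)$receptor
  targets <- data.frame(resno = c(2, 3, 4), h_atom = "HG1", o_atom = "O")
  expect_identical(perturb_polar_charges(rec, targets, delta = 0)$charge,
                   rec$charge)
  pert <- perturb_polar_charges(rec, targets, delta = 0.4)
  h2 <- which(rec$resno == 2 & rec$atom_name == "HG1")
  o2 <- which(rec$resno == 2 & rec$atom_name == "O")
  expect_equal(pert$charge[h2], rec$charge[h2] + 0.4)
  expect_equal(pert$charge[o2], rec$charge[o2] - 0.4)
  for (delta in c(0.1, 0.4, 1.3)) {
    p <- perturb_polar_charges(rec, targets, delta = delta)
    expect_lt(abs(sum(p$charge) - sum(rec$charge)), 1e-9)
    for (rn in targets$resno)
      expect_lt(abs(sum(p$charge[p$resno == rn]) -
                      sum(rec$charge[rec$resno == rn])), 1e-9)
  }
  expect_error(perturb_polar_charges(
    rec, data.frame(resno = 2, h_atom = "HXX", o_atom = "O")), "HXX")
})

test_that("potential solver reproduces the Coulomb closed form in a uniform dielectric", {
  rec <- single_atom_receptor("N", charge = 1)
  lat <- lattice_spec(c(-8, -8, -8), 0.4, c(41, 41, 41))
  dm <- assign_membrane_dielectric(rec, NULL, lat, eps_low = 2, eps_high = 2,
                                   surface_extension = 0)
  phi <- solve_potential_grid(rec, dm, tol = 1e-7)
  for (r in c(1.2, 2, 3, 4, 6, 8)) {
    got <- interp_grid(phi, lat, matrix(c(r, 0, 0), 1))
    expect_lt(abs(got - 332.063 / (2 * r)) / (332.063 / (2 * r)), 0.05)
  }
  # no charges -> identically zero
  rec0 <- single_atom_receptor("C", charge = 0)
  phi0 <- solve_potential_grid(rec0, dm, tol = 1e-7)
  expect_equal(max(abs(phi0)), 0)
})

test_that("discrete Gauss law recovers the enclosed charge within 3 percent", {
  rec <- single_atom_receptor("N", charge = 1)
  lat <- lattice_spec(c(-8, -8, -8), 0.4, c(41, 41, 41))
  dm <- assign_membrane_dielectric(rec, NULL, lat, eps_low = 4, eps_high = 4,
                                   surface_extension = 0)
  phi <- solve_potential_grid(rec, dm, tol = 1e-8)
  # discrete flux through the bonds cut by a centred cube surface:
  # sum eps (phi_out - phi_in) = -4 pi k Q / h at convergence
  h <- lat$spacing
  m <- 10   # cube half-width in nodes
  c0 <- 21  # centre node
  flux <- 0
  rng <- (c0 - m):(c0 + m)
  for (s in c(-1, 1)) {
    i <- c0 + s * m
    for (j in rng) for (k in rng) {
      flux <- flux + 4 * (phi[i + s, j, k] - phi[i, j, k]) +
        4 * (phi[j, i + s, k] - phi[j, i, k]) +
        4 * (phi[j, k, i + s] - phi[j, k, i])
    }
  }
  q_enclosed <- -flux * h / (4 * pi * 332.063)
  expect_lt(abs(q_enclosed - 1), 0.03)
})

test_that("a low-dielectric slab amplifies the potential above it (image-charge bound)", {
  rec <- single_atom_receptor("N", charge = 1)
  lat <- lattice_spec(c(-8, -8, -8), 0.4, c(41, 41, 41))
  # slab of low dielectric filling z < -4, charge at origin (4 A above)
  dm_u <- assign_membrane_dielectric(rec, NULL, lat, eps_low = 78,
                                     eps_high = 78, surface_extension = 0)
  dm_s <- dm_u
  ax_z <- lat$origin[3] + lat$spacing * (seq_len(lat$dims[3]) - 1)
  dm_s$lattice[, , ax_z < -4] <- 2
  phi_u <- solve_potential_grid(rec, dm_u, tol = 1e-7)
  phi_s <- solve_potential_grid(rec, dm_s, tol = 1e-7)
  p <- matrix(c(0, 0, 2), 1)  # 2 A above the charge, opposite the slab
  expect_gt(abs(interp_grid(phi_s, lat, p)), abs(interp_grid(phi_u, lat, p)))
})

test_that("grid construction is translation-equivariant", {
  rec <- random_receptor(10, seed = 3, spread = 3)
  lat <- lattice_spec(c(-8, -8, -8), 0.8, c(21, 21, 21))
  shift <- c(3.7, -1.2, 0.4)
  rec2 <- rec
  rec2$x <- rec$x + shift[1]; rec2$y <- rec$y + shift[2]
  rec2$z <- rec$z + shift[3]
  rec2 <- receptor_model(rec2)
  lat2 <- lattice_spec(lat$origin + shift, lat$spacing, lat$dims)
  v1 <- build_vdw_grid(rec, default_vdw_params(), lat)
  v2 <- build_vdw_grid(rec2, default_vdw_params(), lat2)
  expect_lt(max(abs(v1$vdw_a - v2$vdw_a)), 1e-10 * max(abs(v1$vdw_a)))
  d1 <- assign_membrane_dielectric(rec, NULL, lat)
  d2 <- assign_membrane_dielectric(rec2, NULL, lat2)
  expect_identical(d1$lattice, d2$lattice)
})

test_that("vdW fields equal the direct summation oracle at lattice nodes", {
  rec <- random_receptor(10, seed = 5, spread = 3)
  lat <- lattice_spec(c(-8, -8, -8), 1.0, c(17, 17, 17))
  vg <- build_vdw_grid(rec, default_vdw_params(), lat)
  vp <- default_vdw_params()
  idx <- match(rec$element, vp$element)
  xyz <- as.matrix(rec[, c("x", "y", "z")])
  ax <- seq(-8, 8, by = 1)
  set.seed(8)
  for (probe in seq_len(25)) {
    ijk <- sample(17, 3, replace = TRUE)
    p <- ax[ijk]
    r <- pmax(sqrt(colSums((t(xyz) - p)^2)), 0.8)
    expect_equal(vg$vdw_a[ijk[1], ijk[2], ijk[3]],
                 sum(sqrt(vp$A[idx]) / r^12), tolerance = 1e-10)
    expect_equal(vg$vdw_b[ijk[1], ijk[2], ijk[3]],
                 sum(sqrt(vp$B[idx]) / r^6), tolerance = 1e-10)
  }
  expect_error(build_vdw_grid(single_atom_receptor("X", 0), vp, lat),
               "missing vdW")
})

test_that("interpolated pair energy at the 6-12 minimum matches the closed form", {
  rec <- single_atom_receptor("C", charge = 0, radius = 1.9)
  vp <- default_vdw_params()
  A <- vp$A[vp$element == "C"]; B <- vp$B[vp$element == "C"]
  rmin <- (2 * A / B)^(1 / 6)
  emin <- -B^2 / (4 * A)
  lat <- lattice_spec(c(-0.5, -0.5, -0.5), 0.1, c(51, 11, 11))
  vg <- build_vdw_grid(rec, vp, lat)
  e <- sqrt(A) * interp_grid(vg$vdw_a, lat, matrix(c(rmin, 0, 0), 1)) -
    sqrt(B) * interp_grid(vg$vdw_b, lat, matrix(c(rmin, 0, 0), 1))
  expect_lt(abs(e - emin) / abs(emin), 0.02)
})

test_that("desolvation occlusion spans bulk solvent to buried interior and matches Monte Carlo", {
  # tight 3x3x3 block of fat atoms: centre is fully buried
  g <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  rec <- receptor_model(data.frame(
    element = "C", x = g$x, y = g$y, z = g$z, radius = 1.9, charge = 0,
    atom_name = "CA", resname = "GLY", resno = seq_len(27), chain = "A"))
  lat <- lattice_spec(c(-8, -8, -8), 1.0, c(17, 17, 17))
  dg <- build_desolvation_grid(rec, NULL, lat, volume_extension = 0.5,
                               shell_radius = 1.8, n_sub = 6)
  expect_equal(dg$occlusion[1, 1, 1], 0)          # bulk solvent corner
  expect_equal(dg$occlusion[9, 9, 9], 1)          # block centre
  expect_true(all(dg$occlusion >= 0 & dg$occlusion <= 1))
  # mid-surface node vs a dense Monte-Carlo oracle
  node <- c(4, 0, 0)  # near the +x face of the block
  got <- dg$occlusion[13, 9, 9]
  set.seed(99)
  u <- matrix(stats::rnorm(3e5), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sp <- sweep(u * (1.8 * stats::runif(1e5)^(1 / 3)), 2, node, "+")
  xyz <- as.matrix(rec[, c("x", "y", "z")])
  inside <- rep(FALSE, 1e5)
  for (a in seq_len(27))
    inside <- inside | rowSums(sweep(sp, 2, xyz[a, ])^2) <= 2.4^2
  expect_lt(abs(got - mean(inside)), 0.02)
})

test_that("matching spheres deduplicate and truncate toward the centroid", {
  pts10 <- matrix(stats::rnorm(30, sd = 4), 10, 3)
  expect_equal(nrow(generate_matching_spheres(pts10)$centers), 10)
  set.seed(2)
  pts50 <- matrix(stats::rnorm(150, sd = 4), 50, 3)
  ms <- generate_matching_spheres(pts50, max_spheres = 45)
  expect_equal(nrow(ms$centers), 45)
  # the 45 kept are the closest to the centroid
  cen <- colMeans(pts50)
  d <- sqrt(colSums((t(pts50) - cen)^2))
  expect_lte(max(sqrt(colSums((t(ms$centers) - cen)^2))),
             sort(d)[46] + 1e-12)
  near <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(5, 0, 0))
  expect_equal(nrow(generate_matching_spheres(near,
                                              dedup_radius = 0.5)$centers), 2)
  expect_error(generate_matching_spheres(matrix(0, 2, 3)), "at least 3")
})

test_that("receptor PDB + parameter-table round trip preserves the model", {
  tc <- make_toy_complex(30, 15, seed = 5)
  pdb <- tempfile(fileext = ".pdb")
  par <- tempfile(fileext = ".txt")
  write_receptor_pdb(tc$receptor, pdb, lipid_atoms = tc$lipid_atoms)
  receptor_param_table(tc$receptor, par)
  rec2 <- read_receptor_pdb(pdb, par)
  expect_equal(nrow(rec2), nrow(tc$receptor))
  expect_equal(rec2$x, tc$receptor$x, tolerance = 1e-3)
  expect_equal(rec2$charge, tc$receptor$charge)
  expect_equal(rec2$radius, tc$receptor$radius)
  lip2 <- attr(rec2, "lipid_atoms")
  expect_equal(nrow(lip2), nrow(tc$lipid_atoms))
  expect_equal(unname(lip2), unname(tc$lipid_atoms), tolerance = 1e-3)
})
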