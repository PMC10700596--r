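# Membrane-aware scoring grids.
#
# All lattices are node-centred regular grids (lattice_spec). Energies are
# kcal/mol, charges elementary units, lengths Angstrom. The electrostatic
# conversion constant 332.063 kcal*A/(mol*e^2) converts q*q/r to kcal/mol.

COULOMB_K <- 332.063

#' Membrane-aware two-level dielectric map
#'
#' Classifies every lattice node as low dielectric (receptor or lipid
#' interior) or high dielectric (aqueous). A node is low-dielectric iff it
#' lies within \code{atom radius + surface_extension} of any receptor atom,
#' or within \code{lipid_radius} of any retained lipid atom. Lipid atoms
#' farther than \code{lipid_cutoff} from every receptor atom are discarded
#' before classification, reproducing the "low-dielectric ring" construction
#' around a membrane-embedded receptor.
#'
#' @param receptor a \code{\link{receptor_model}}.
#' @param lipid_atoms n x 3 matrix of lipid apolar-atom coordinates (may be
#'   NULL or empty).
#' @param box a \code{\link{lattice_spec}} covering the receptor.
#' @param lipid_cutoff discard lipid atoms farther than this from every
#'   receptor atom, Angstrom (default 17).
#' @param surface_extension outward extension of the receptor low-dielectric
#'   surface, Angstrom (default 1.9).
#' @param eps_low,eps_high the two relative dielectric values (defaults 2
#'   and 78).
#' @param lipid_radius radius assigned to lipid apolar atoms, Angstrom
#'   (default 1.7; lipid atoms are not inflated by \code{surface_extension}).
#' @return Object of class \code{dielectric_map}: list with the epsilon
#'   \code{lattice} (3D array), the \code{spec}, \code{eps_low},
#'   \code{eps_high} and the retained lipid atoms.
#' @export
assign_membrane_dielectric <- function(receptor, lipid_atoms, box,
                                       lipid_cutoff = 17,
                                       surface_extension = 1.9,
                                       eps_low = 2, eps_high = 78,
                                       lipid_radius = 1.7) {
  stopifnot(inherits(box, "lattice_spec"))
  if (!inherits(receptor, "receptor_model") || nrow(receptor) == 0L)
    stop("receptor must be a non-empty receptor_model")
  xyz <- receptor_coords(receptor)
  if (!lattice_covers(box, xyz))
    stop("lattice does not cover the receptor")
  lip <- normalize_points(lipid_atoms)
  if (nrow(lip) > 0) {
    # retain only lipid atoms within lipid_cutoff of some receptor atom
    keep <- vapply(seq_len(nrow(lip)), function(i) {
      d2 <- (xyz[, 1] - lip[i, 1])^2 + (xyz[, 2] - lip[i, 2])^2 +
        (xyz[, 3] - lip[i, 3])^2
      min(d2) <= lipid_cutoff^2
    }, logical(1))
    lip <- lip[keep, , drop = FALSE]
  }
  inside <- lattice_inside_cpp(box$origin, box$spacing, box$dims,
                               xyz, receptor$radius, surface_extension)
  if (nrow(lip) > 0) {
    inside_lip <- lattice_inside_cpp(box$origin, box$spacing, box$dims,
                                     lip, rep(lipid_radius, nrow(lip)), 0)
    inside <- inside | inside_lip
  }
  lattice <- array(ifelse(inside, eps_low, eps_high), dim = box$dims)
  structure(list(lattice = lattice, spec = box, eps_low = eps_low,
                 eps_high = eps_high, lipid_atoms = lip),
            class = "dielectric_map")
}

#' @export
print.dielectric_map <- function(x, ...) {
  frac <- mean(x$lattice == x$eps_low)
  cat(sprintf("dielectric map: %d x %d x %d, eps {%g, %g}, %.1f%% low-dielectric\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3],
              x$eps_low, x$eps_high, 100 * frac))
  invisible(x)
}

normalize_points <- function(p) {
  if (is.null(p) || length(p) == 0) return(matrix(numeric(0), ncol = 3))
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("point sets must have 3 columns")
  storage.mode(p) <- "double"
  p
}

#' Perturb polar sidechain/backbone charge pairs
#'
#' Increases the partial charge of a sidechain hydroxyl hydrogen and
#' decreases the charge of the same residue's backbone carbonyl oxygen by the
#' same amount, strengthening the local dipole while leaving the residue (and
#' receptor) net charge unchanged. This is the anion-recognition charge
#' perturbation applied to pocket threonines/tyrosines.
#'
#' @param receptor a \code{\link{receptor_model}}.
#' @param targets data.frame with columns \code{resno}, \code{h_atom},
#'   \code{o_atom} (atom names of the hydroxyl hydrogen and backbone oxygen).
#' @param delta charge increment in elementary units (default 0.4).
#' @return A new \code{receptor_model} with perturbed charges.
#' @export
perturb_polar_charges <- function(receptor, targets, delta = 0.4) {
  stopifnot(inherits(receptor, "receptor_model"))
  out <- receptor
  for (i in seq_len(nrow(targets))) {
    resno <- targets$resno[i]
    hi <- which(out$resno == resno & out$atom_name == targets$h_atom[i])
    oi <- which(out$resno == resno & out$atom_name == targets$o_atom[i])
    if (length(hi) != 1L)
      stop(sprintf("residue %s: hydroxyl atom '%s' not found (or ambiguous)",
                   resno, targets$h_atom[i]))
    if (length(oi) != 1L)
      stop(sprintf("residue %s: backbone oxygen '%s' not found (or ambiguous)",
                   resno, targets$o_atom[i]))
    out$charge[hi] <- out$charge[hi] + delta
    out$charge[oi] <- out$charge[oi] - delta
  }
  attr(out, "net_charge") <- sum(out$charge)
  out
}

#' Finite-difference Poisson electrostatic potential
#'
#' Solves div(eps grad phi) = -4 pi k rho on the dielectric map's lattice at
#' zero ionic strength, with Dirichlet boundary values from the Coulomb
#' potential in the high-dielectric medium. Atom charges are spread onto the
#' eight surrounding nodes by trilinear weights. The result is the potential
#' in kcal/(mol e) sampled at lattice nodes.
#'
#' @param receptor a \code{\link{receptor_model}} (all charged atoms must lie
#'   strictly inside the lattice).
#' @param dielectric a \code{dielectric_map}.
#' @param tol relative residual tolerance (default 1e-6).
#' @param maxiter maximum SOR sweeps (default 10000).
#' @return 3D array of potential values with attributes \code{spec},
#'   \code{residual}, \code{iterations}.
#' @export
solve_potential_grid <- function(receptor, dielectric, tol = 1e-6,
                                 maxiter = 10000L) {
  stopifnot(inherits(dielectric, "dielectric_map"))
  lat <- dielectric$spec
  xyz <- receptor_coords(receptor)
  q <- receptor$charge
  charged <- abs(q) > 0
  if (any(charged) && !lattice_covers(lat, xyz[charged, , drop = FALSE],
                                      clearance = lat$spacing))
    stop("charged atoms must lie strictly inside the lattice")
  dims <- lat$dims
  h <- lat$spacing
  rho <- array(0, dim = dims)
  for (a in which(charged)) {
    w <- trilinear_weights(lat, xyz[a, ])
    rho[w$idx] <- rho[w$idx] + q[a] * w$w
  }
  # Dirichlet boundary: Coulomb sum in the aqueous dielectric
  phi0 <- array(0, dim = dims)
  if (any(charged)) {
    bidx <- boundary_indices(dims)
    bxyz <- cbind(lat$origin[1] + (bidx[, 1] - 1) * h,
                  lat$origin[2] + (bidx[, 2] - 1) * h,
                  lat$origin[3] + (bidx[, 3] - 1) * h)
    val <- numeric(nrow(bidx))
    for (a in which(charged)) {
      r <- sqrt((bxyz[, 1] - xyz[a, 1])^2 + (bxyz[, 2] - xyz[a, 2])^2 +
                (bxyz[, 3] - xyz[a, 3])^2)
      r <- pmax(r, h)
      val <- val + COULOMB_K * q[a] / (dielectric$eps_high * r)
    }
    phi0[bidx] <- val
  }
  omega <- 2 / (1 + sin(pi / max(dims)))
  sol <- poisson_sor_cpp(as.numeric(dielectric$lattice), as.numeric(rho),
                         as.numeric(phi0), dims, h, 4 * pi * COULOMB_K,
                         tol, as.integer(maxiter), omega)
  if (sol$residual >= tol && any(charged))
    stop(sprintf("Poisson solver did not converge: relative residual %.3g after %d sweeps",
                 sol$residual, sol$iterations))
  structure(sol$phi, spec = lat, residual = sol$residual,
            iterations = sol$iterations)
}

boundary_indices <- function(dims) {
  ii <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                    k = seq_len(dims[3]))
  on_b <- ii$i == 1L | ii$i == dims[1] | ii$j == 1L | ii$j == dims[2] |
    ii$k == 1L | ii$k == dims[3]
  as.matrix(ii[on_b, ])
}

# trilinear spreading / interpolation weights for a point inside the lattice
trilinear_weights <- function(lat, p) {
  g <- (p - lat$origin) / lat$spacing
  i0 <- pmin(pmax(floor(g), 0), lat$dims - 2)
  f <- g - i0
  i0 <- as.integer(i0) + 1L  # 1-based lower corner
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  idx <- cbind(i0[1] + corners[, 1], i0[2] + corners[, 2], i0[3] + corners[, 3])
  w <- apply(corners, 1, function(cc) {
    prod(ifelse(cc == 1, f, 1 - f))
  })
  list(idx = idx, w = w)
}

#' Trilinear interpolation of a lattice field at arbitrary points
#'
#' @param field 3D array sampled on \code{spec} nodes.
#' @param spec the \code{lattice_spec}.
#' @param pts n x 3 matrix of query points; all must lie inside the lattice.
#' @return numeric vector of interpolated values.
#' @export
interp_grid <- function(field, spec, pts) {
  pts <- normalize_points(pts)
  if (!lattice_covers(spec, pts))
    stop("query point outside the lattice")
  vapply(seq_len(nrow(pts)), function(i) {
    w <- trilinear_weights(spec, pts[i, ])
    sum(field[w$idx] * w$w)
  }, numeric(1))
}

#' AMBER-style van der Waals scoring grids
#'
#' Precomputes the two lattice sums of the 6-12 potential so a ligand atom
#' with coefficients (sqrt A_i, sqrt B_i) scores
#' \code{sqrtA_i * vdw_a(x) - sqrtB_i * vdw_b(x)} by interpolation:
#' \code{vdw_a(x) = sum_j sqrt(A_j) / r_jx^12},
#' \code{vdw_b(x) = sum_j sqrt(B_j) / r_jx^6}. Distances are floored at
#' \code{r_floor} to cap the singularity at atom centres. Lipid atoms must
#' not be included in the receptor passed here.
#'
#' @param receptor a \code{\link{receptor_model}}.
#' @param vdw_params data.frame with columns \code{element}, \code{A},
#'   \code{B} (AMBER 6-12 coefficients, kcal/mol * A^12 and kcal/mol * A^6).
#' @param lattice a \code{\link{lattice_spec}}.
#' @param r_floor distance floor in Angstrom (default 0.8).
#' @return list with 3D arrays \code{vdw_a}, \code{vdw_b} and the
#'   \code{spec}.
#' @export
build_vdw_grid <- function(receptor, vdw_params, lattice, r_floor = 0.8) {
  stopifnot(inherits(lattice, "lattice_spec"))
  dims <- lattice$dims
  va <- array(0, dim = dims)
  vb <- array(0, dim = dims)
  if (nrow(receptor) > 0) {
    idx <- match(receptor$element, vdw_params$element)
    if (anyNA(idx))
      stop("missing vdW parameters for element(s): ",
           paste(unique(receptor$element[is.na(idx)]), collapse = ", "))
    ax <- lattice_axes(lattice)
    xyz <- receptor_coords(receptor)
    sqA <- sqrt(vdw_params$A[idx])
    sqB <- sqrt(vdw_params$B[idx])
    # per-atom accumulation over the full lattice (desk-scale boxes)
    dx2 <- outer(ax[[1]], xyz[, 1], function(g, a) (g - a)^2)
    dy2 <- outer(ax[[2]], xyz[, 2], function(g, a) (g - a)^2)
    dz2 <- outer(ax[[3]], xyz[, 3], function(g, a) (g - a)^2)
    for (a in seq_len(nrow(receptor))) {
      r2 <- outer(outer(dx2[, a], dy2[, a], "+"), dz2[, a], "+")
      r2 <- pmax(r2, r_floor^2)
      inv6 <- 1 / r2^3
      va <- va + sqA[a] * inv6 * inv6
      vb <- vb + sqB[a] * inv6
    }
  }
  list(vdw_a = va, vdw_b = vb, spec = lattice)
}

#' Default united-atom 6-12 coefficients
#'
#' A compact AMBER-style parameter set (A in kcal/mol * A^12, B in
#' kcal/mol * A^6) for the pseudo-elements used by the toy receptors plus
#' common organic elements. Values are of the magnitude of united-atom AMBER
#' parameters; they define the package's test chemistry, not a force field.
#'
#' @return data.frame with columns \code{element}, \code{A}, \code{B}.
#' @export
default_vdw_params <- function() {
  data.frame(
    element = c("C", "N", "O", "S", "H", "P", "F"),
    A = c(1043080, 540675, 230584, 1302430, 81.6, 1302430, 130000),
    B = c(675.61, 588.24, 429.50, 1179.63, 2.06, 1179.63, 320.0),
    stringsAsFactors = FALSE)
}

#' Ligand-desolvation occlusion grid
#'
#' For every lattice node, the occlusion is the fraction of a deterministic
#' set of sample points in a ball of \code{shell_radius} around the node that
#' fall inside the combined receptor-plus-lipid volume, with the receptor
#' surface extended outward by \code{volume_extension}. Occlusion near 1
#' means a ligand atom placed there is buried (its desolvation penalty is
#' charged in full); 0 means fully solvated.
#'
#' @param receptor a \code{\link{receptor_model}}.
#' @param lipid_atoms n x 3 matrix of lipid coordinates (may be NULL).
#' @param lattice a \code{\link{lattice_spec}}.
#' @param volume_extension outward extension of the receptor volume,
#'   Angstrom (default 0.5).
#' @param shell_radius radius of the sampling ball, Angstrom.
#' @param n_sub sample ball resolution: points are taken on a cubic subgrid
#'   of step \code{shell_radius / n_sub} (default 6).
#' @param lipid_radius radius of lipid atoms, Angstrom (default 1.7; lipid
#'   volume is not extended).
#' @return list with 3D array \code{occlusion} in [0, 1] and the \code{spec}.
#' @export
build_desolvation_grid <- function(receptor, lipid_atoms, lattice,
                                   volume_extension = 0.5, shell_radius = 1.8,
                                   n_sub = 6L, lipid_radius = 1.7) {
  stopifnot(inherits(lattice, "lattice_spec"))
  ball <- ball_sample_points(shell_radius, n_sub)
  lip <- normalize_points(lipid_atoms)
  pts <- rbind(receptor_coords(receptor), lip)
  radii <- c(receptor$radius + volume_extension,
             rep(lipid_radius, nrow(lip)))
  occ <- occlusion_grid_cpp(lattice$origin, lattice$spacing, lattice$dims,
                            ball, pts, radii)
  list(occlusion = occ, spec = lattice)
}

# deterministic cubic-subgrid sample of the unit ball scaled to radius
ball_sample_points <- function(radius, n_sub) {
  s <- seq(-1, 1, length.out = 2L * n_sub + 1L)
  g <- as.matrix(expand.grid(s, s, s))
  g <- g[rowSums(g^2) <= 1, , drop = FALSE]
  g * radius
}

# fraction of (node + ball offsets) falling inside any inflated sphere
occlusion_at_points <- function(nodes, ball, pts, radii) {
  if (nrow(pts) == 0) return(rep(0, nrow(nodes)))
  vapply(seq_len(nrow(nodes)), function(i) {
    sp <- sweep(ball, 2, nodes[i, ], "+")
    inside <- rep(FALSE, nrow(sp))
    for (a in seq_len(nrow(pts))) {
      d2 <- (sp[, 1] - pts[a, 1])^2 + (sp[, 2] - pts[a, 2])^2 +
        (sp[, 3] - pts[a, 3])^2
      inside <- inside | d2 <= radii[a]^2
      if (all(inside)) break
    }
    mean(inside)
  }, numeric(1))
}

#' Matching spheres from reference ligand atoms
#'
#' Sphere centres are the reference heavy-atom positions, deduplicated at
#' \code{dedup_radius} and truncated to \code{max_spheres}, keeping atoms
#' closest to the reference centroid first (the pocket core).
#'
#' @param reference_atoms n x 3 matrix of reference ligand heavy-atom
#'   coordinates (n >= 3).
#' @param max_spheres maximum number of spheres (default 45).
#' @param dedup_radius minimum pairwise centre distance, Angstrom
#'   (default 0.25).
#' @return Object of class \code{matching_spheres}: list with \code{centers}
#'   (m x 3 matrix) and the parameters.
#' @export
generate_matching_spheres <- function(reference_atoms, max_spheres = 45L,
                                      dedup_radius = 0.25) {
  pts <- normalize_points(reference_atoms)
  if (nrow(pts) < 3L) stop("at least 3 reference atoms are required")
  centroid <- colMeans(pts)
  ord <- order(sqrt(colSums((t(pts) - centroid)^2)))
  kept <- matrix(numeric(0), ncol = 3)
  for (i in ord) {
    p <- pts[i, ]
    if (nrow(kept) == 0 ||
        min(sqrt(colSums((t(kept) - p)^2))) >= dedup_radius)
      kept <- rbind(kept, p)
    if (nrow(kept) >= max_spheres) break
  }
  rownames(kept) <- NULL
  structure(list(centers = kept, max_spheres = as.integer(max_spheres),
                 dedup_radius = dedup_radius),
            class = "matching_spheres")
}

#' @export
print.matching_spheres <- function(x, ...) {
  cat(sprintf("matching spheres: %d centres (max %d, dedup %.2f A)\n",
              nrow(x$centers), x$max_spheres, x$dedup_radius))
  invisible(x)
}

#' Assemble the scoring grids used by the docking engine
#'
#' Convenience wrapper running the full grid recipe: dielectric map (with
#' lipid ring), optional polar-charge perturbation, Poisson potential, vdW
#' lattices (receptor only), desolvation occlusion (receptor + lipids) and
#' matching spheres.
#'
#' @param receptor a \code{\link{receptor_model}}.
#' @param lipid_atoms lipid apolar-atom coordinates.
#' @param reference_atoms reference ligand atoms for matching spheres.
#' @param lattice a \code{\link{lattice_spec}}; default built around the
#'   receptor.
#' @param polar_targets optional data.frame for
#'   \code{\link{perturb_polar_charges}}.
#' @param delta_q polar perturbation magnitude, e (default 0.4).
#' @param lipid_cutoff,surface_extension,eps_low,eps_high,volume_extension
#'   grid-recipe parameters, see the individual builders.
#' @param vdw_params 6-12 coefficients (default
#'   \code{\link{default_vdw_params}}).
#' @param tol Poisson solver tolerance.
#' @return Object of class \code{scoring_grids}: potential, vdw_a, vdw_b,
#'   occlusion (3D arrays sharing \code{spec}), plus \code{spheres} and the
#'   dielectric map.
#' @export
build_scoring_grids <- function(receptor, lipid_atoms, reference_atoms,
                                lattice = lattice_around(receptor),
                                polar_targets = NULL, delta_q = 0.4,
                                lipid_cutoff = 17, surface_extension = 1.9,
                                eps_low = 2, eps_high = 78,
                                volume_extension = 0.5,
                                vdw_params = default_vdw_params(),
                                tol = 1e-6) {
  if (!is.null(polar_targets) && nrow(polar_targets) > 0)
    receptor <- perturb_polar_charges(receptor, polar_targets, delta = delta_q)
  diel <- assign_membrane_dielectric(receptor, lipid_atoms, lattice,
                                     lipid_cutoff = lipid_cutoff,
                                     surface_extension = surface_extension,
                                     eps_low = eps_low, eps_high = eps_high)
  pot <- solve_potential_grid(receptor, diel, tol = tol)
  vdw <- build_vdw_grid(receptor, vdw_params, lattice)
  des <- build_desolvation_grid(receptor, lipid_atoms, lattice,
                                volume_extension = volume_extension)
  spheres <- generate_matching_spheres(reference_atoms)
  structure(list(potential = unclass(pot), vdw_a = vdw$vdw_a,
                 vdw_b = vdw$vdw_b, occlusion = des$occlusion,
                 spec = lattice, spheres = spheres, dielectric = diel,
                 receptor = receptor),
            class = "scoring_grids")
}

#' @export
print.scoring_grids <- function(x, ...) {
  cat(sprintf("scoring grids on %d x %d x %d lattice (spacing %.2f A), %d matching spheres\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3], x$spec$spacing,
              nrow(x$spheres$centers)))
  invisible(x)
}
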