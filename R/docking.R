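# Rigid-conformer docking: orientations are generated by superposing ligand
# heavy-atom triplets onto matching-sphere triplets (least-squares rigid
# fit), and each pose is scored on the precomputed grids with the three-term
# physics score  E = E_elec + E_vdw + E_desolv.

#' Construct a ligand conformer
#'
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (Angstrom), \code{charge} (e), \code{desolv} (per-atom
#'   desolvation penalty magnitude, kcal/mol, >= 0), \code{sqrtA},
#'   \code{sqrtB} (square roots of the atom's 6-12 coefficients).
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @param id conformer identifier.
#' @return Object of class \code{ligand_conformer}.
#' @export
ligand_conformer <- function(atoms, bonds = NULL, id = "lig") {
  required <- c("element", "x", "y", "z", "charge", "desolv", "sqrtA", "sqrtB")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("conformer atom table lacks column(s): ", paste(missing, collapse = ", "))
  heavy <- atoms$element != "H"
  if (sum(heavy) < 3L) stop("a conformer needs at least 3 heavy atoms")
  if (any(atoms$desolv < 0))
    stop("desolvation penalties are stored as non-negative magnitudes")
  structure(list(atoms = as.data.frame(atoms), bonds = bonds, id = id),
            class = "ligand_conformer")
}

#' @export
print.ligand_conformer <- function(x, ...) {
  cat(sprintf("ligand conformer '%s': %d atoms (%d heavy), net charge %+.2f e\n",
              x$id, nrow(x$atoms), sum(x$atoms$element != "H"),
              sum(x$atoms$charge)))
  invisible(x)
}

conformer_coords <- function(conf) as.matrix(conf$atoms[, c("x", "y", "z")])

# Kabsch least-squares rigid superposition of points A onto B (n x 3 each);
# returns proper rotation R and translation t with  B ~ A %*% R + t.
kabsch_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R <- t(R)  # so that  A %*% R  maps into B's frame
  t <- cb - ca %*% R
  list(R = R, t = as.numeric(t))
}

#' Enumerate ligand orientations on the matching spheres
#'
#' Every heavy-atom triplet (lexicographic in atom indices) is compared to
#' every ordered sphere triplet (lexicographic in sphere indices); when the
#' three corresponding pairwise distances agree within \code{distance_tol},
#' a least-squares rigid fit of the triplet generates a pose. Enumeration
#' order is deterministic and output is truncated at
#' \code{max_orientations}.
#'
#' @param conformer a \code{\link{ligand_conformer}}.
#' @param spheres a \code{\link{generate_matching_spheres}} result.
#' @param distance_tol pairwise-distance match tolerance, Angstrom (>= 0,
#'   default 0.5).
#' @param max_orientations maximum number of poses (default 1000).
#' @return list of poses, each of class \code{pose}: list with \code{R}
#'   (rotation), \code{t} (translation), \code{coords} (transformed atom
#'   coordinates), \code{conformer_id}, and the matched triplets. An empty
#'   list means no compatible triplet exists.
#' @export
orient_ligand <- function(conformer, spheres, distance_tol = 0.5,
                          max_orientations = 1000L) {
  if (distance_tol < 0) stop("distance_tol must be non-negative")
  centers <- spheres$centers
  if (nrow(centers) < 3L) stop("at least 3 matching spheres are required")
  xyz <- conformer_coords(conformer)
  heavy <- which(conformer$atoms$element != "H")
  poses <- list()
  n <- length(heavy); m <- nrow(centers)
  atrip <- utils::combn(heavy, 3)
  strip <- sphere_triplets(m)
  dl <- as.matrix(stats::dist(xyz))
  ds <- as.matrix(stats::dist(centers))
  for (ai in seq_len(ncol(atrip))) {
    a <- atrip[, ai]
    la <- c(dl[a[1], a[2]], dl[a[1], a[3]], dl[a[2], a[3]])
    for (si in seq_len(nrow(strip))) {
      s <- strip[si, ]
      ls <- c(ds[s[1], s[2]], ds[s[1], s[3]], ds[s[2], s[3]])
      if (all(abs(la - ls) <= distance_tol)) {
        fit <- kabsch_fit(xyz[a, , drop = FALSE], centers[s, , drop = FALSE])
        coords <- sweep(xyz %*% fit$R, 2, -fit$t)
        poses[[length(poses) + 1L]] <- structure(
          list(R = fit$R, t = fit$t, coords = coords,
               conformer_id = conformer$id, atom_triplet = a,
               sphere_triplet = s),
          class = "pose")
        if (length(poses) >= max_orientations) return(poses)
      }
    }
  }
  poses
}

# ordered sphere triplets (distinct indices), lexicographic
sphere_triplets <- function(m) {
  g <- expand.grid(k = seq_len(m), j = seq_len(m), i = seq_len(m))
  g <- g[g$i != g$j & g$i != g$k & g$j != g$k, c("i", "j", "k")]
  g <- g[order(g$i, g$j, g$k), ]
  as.matrix(g)
}

#' Score a pose on the grids
#'
#' Three-term physics score by trilinear interpolation at the transformed
#' atom positions: probe-charge electrostatics
#' \code{E_elec = sum q_i phi(x_i)}, AMBER-style 6-12
#' \code{E_vdw = sum (sqrtA_i vdw_a(x_i) - sqrtB_i vdw_b(x_i))} with the
#' per-atom repulsion capped, and context desolvation
#' \code{E_desolv = sum desolv_i occlusion(x_i)} (a penalty, >= 0).
#'
#' @param pose a \code{pose} from \code{\link{orient_ligand}}.
#' @param conformer the \code{\link{ligand_conformer}} the pose transforms.
#' @param grids a \code{\link{build_scoring_grids}} result.
#' @param vdw_cap per-atom repulsive cap, kcal/mol (default 100).
#' @return Object of class \code{score_breakdown}: list with \code{e_elec},
#'   \code{e_vdw}, \code{e_desolv}, \code{e_total} (kcal/mol).
#' @export
score_pose <- function(pose, conformer, grids, vdw_cap = 100) {
  pts <- pose$coords
  if (!lattice_covers(grids$spec, pts)) {
    bad <- which(!apply(
      sweep(pts, 2, grids$spec$origin, ">=") &
        sweep(pts, 2, lattice_max(grids$spec), "<="), 1, all))[1]
    stop(sprintf("atom %d lies outside the scoring grids", bad))
  }
  at <- conformer$atoms
  phi <- interp_grid(grids$potential, grids$spec, pts)
  va <- interp_grid(grids$vdw_a, grids$spec, pts)
  vb <- interp_grid(grids$vdw_b, grids$spec, pts)
  occ <- interp_grid(grids$occlusion, grids$spec, pts)
  e_elec <- sum(at$charge * phi)
  e_vdw <- sum(pmin(at$sqrtA * va - at$sqrtB * vb, vdw_cap))
  e_desolv <- sum(at$desolv * occ)
  structure(list(e_elec = e_elec, e_vdw = e_vdw, e_desolv = e_desolv,
                 e_total = e_elec + e_vdw + e_desolv),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("E_total %8.3f = elec %8.3f + vdw %8.3f + desolv %7.3f kcal/mol\n",
              x$e_total, x$e_elec, x$e_vdw, x$e_desolv))
  invisible(x)
}

#' Dock one molecule: best pose over all conformers and orientations
#'
#' @param conformers list of \code{\link{ligand_conformer}}s (>= 1).
#' @param grids scoring grids.
#' @param spheres matching spheres (default the grids' own).
#' @param distance_tol,max_orientations orientation-search parameters.
#' @param vdw_cap per-atom repulsive cap.
#' @return list with \code{placed} (logical), and when placed: \code{pose},
#'   \code{score} (a \code{score_breakdown}), \code{conformer_id}. Ties are
#'   broken by enumeration order.
#' @export
dock_molecule <- function(conformers, grids, spheres = grids$spheres,
                          distance_tol = 0.5, max_orientations = 1000L,
                          vdw_cap = 100) {
  if (!length(conformers)) stop("at least one conformer is required")
  if (inherits(conformers, "ligand_conformer")) conformers <- list(conformers)
  best <- list(placed = FALSE, pose = NULL, score = NULL, conformer_id = NA)
  for (conf in conformers) {
    poses <- orient_ligand(conf, spheres, distance_tol, max_orientations)
    for (p in poses) {
      sc <- try(score_pose(p, conf, grids, vdw_cap), silent = TRUE)
      if (inherits(sc, "try-error")) next   # pose fell outside the box
      if (!best$placed || sc$e_total < best$score$e_total) {
        best <- list(placed = TRUE, pose = p, score = sc,
                     conformer_id = conf$id)
      }
    }
  }
  best
}

#' Rank a library by best docking score
#'
#' @param library named list: each element is a list of conformers for one
#'   molecule (or a single \code{ligand_conformer}).
#' @param grids,spheres,distance_tol,max_orientations,vdw_cap passed to
#'   \code{\link{dock_molecule}}.
#' @return data.frame (id, e_elec, e_vdw, e_desolv, e_total, placed, rank),
#'   sorted ascending by \code{e_total} with unplaced molecules flagged and
#'   listed last; input order breaks ties (stable sort).
#' @export
rank_library <- function(library, grids, spheres = grids$spheres,
                         distance_tol = 0.5, max_orientations = 1000L,
                         vdw_cap = 100) {
  if (!length(library)) stop("library must be non-empty")
  ids <- names(library) %||% sprintf("mol%04d", seq_along(library))
  rows <- lapply(seq_along(library), function(i) {
    res <- dock_molecule(library[[i]], grids, spheres, distance_tol,
                         max_orientations, vdw_cap)
    if (res$placed)
      data.frame(id = ids[i], e_elec = res$score$e_elec,
                 e_vdw = res$score$e_vdw, e_desolv = res$score$e_desolv,
                 e_total = res$score$e_total, placed = TRUE,
                 stringsAsFactors = FALSE)
    else
      data.frame(id = ids[i], e_elec = NA_real_, e_vdw = NA_real_,
                 e_desolv = NA_real_, e_total = NA_real_, placed = FALSE,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(!out$placed, out$e_total, seq_len(nrow(out)), na.last = FALSE)
  # stable: placed ascending by score (ties input order), unplaced last
  ord <- c(which(out$placed)[order(out$e_total[out$placed])],
           which(!out$placed))
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
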