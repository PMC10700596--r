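# Seeded fixture generators. Every stage of the pipeline can run on the
# objects produced here: a toy membrane-embedded receptor, compound libraries
# with known class composition, planted enrichment benchmarks, 4PL assay
# data and one-compartment PK profiles.

#' Toy membrane-embedded receptor complex
#'
#' Builds a rigid cluster of united-atom pseudo-atoms forming a concave
#' pocket around the origin, flanked by a lipid slab: two parallel planes of
#' apolar points at z = +/- slab_z / 2 on an 8 Angstrom lateral raster, with
#' the points over the pocket mouth (the +z face) removed. Charges are
#' hand-assigned in {-0.4, 0, +0.4, +1} e and radii in {1.5, 1.9} Angstrom:
#' a +1 "arginine-like" nitrogen sits at the pocket bottom and three
#' serine/threonine-like residues contribute hydroxyl-hydrogen (+0.4) /
#' backbone-oxygen (-0.4) pairs, so the complex spans the charge-perturbation
#' and anion-recognition test space without a force field.
#'
#' @param n_receptor_atoms total receptor atom count (>= 10).
#' @param slab_z slab thickness: lipid planes sit at +/- slab_z / 2, and all
#'   lipid points satisfy |z| <= slab_z.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return Object of class \code{toy_complex}: list with \code{receptor}
#'   (a \code{\link{receptor_model}}), \code{lipid_atoms} (n x 3 matrix),
#'   \code{pocket_center}, \code{reference_ligand_atoms} and \code{slab_z}.
#' @export
make_toy_complex <- function(n_receptor_atoms = 50L, slab_z = 15,
                             seed = 1L) {
  if (!is.numeric(n_receptor_atoms) || n_receptor_atoms < 10)
    stop("n_receptor_atoms must be at least 10")
  if (slab_z <= 0) stop("slab_z must be positive")
  n <- as.integer(n_receptor_atoms)
  with_seed(seed, {
    # functional core: 1 cationic N + three hydroxyl/backbone-O pairs + a CA
    # each, near the pocket wall (pocket centre is the origin, mouth at +z)
    core <- data.frame(
      element   = c("N", "H", "O", "C", "H", "O", "C", "H", "O", "C"),
      x         = c(0.0,  3.8, 4.9, 4.6, -3.8, -4.9, -4.6, 0.2, 1.2, 0.8),
      y         = c(0.2,  1.2, 2.2, 0.4, 1.0,  2.1,  0.5, -4.0, -5.2, -4.9),
      z         = c(-4.5, -1.0, -0.2, -2.4, -1.2, -0.4, -2.6, -0.8, 0.1, -2.5),
      radius    = c(1.5, 1.5, 1.5, 1.9, 1.5, 1.5, 1.9, 1.5, 1.5, 1.9),
      charge    = c(1, 0.4, -0.4, 0, 0.4, -0.4, 0, 0.4, -0.4, 0),
      atom_name = c("NH1", "HG1", "O", "CA", "HG1", "O", "CA", "HG1", "O", "CA"),
      resname   = c("ARG", "THR", "THR", "THR", "TYR", "TYR", "TYR",
                    "THR", "THR", "THR"),
      resno     = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
      chain     = "A", stringsAsFactors = FALSE)
    # shell atoms: apolar wall on a sphere of radius ~6 A around the pocket,
    # leaving a cone open toward +z (the mouth)
    n_shell <- n - nrow(core)
    u <- stats::runif(n_shell, -1, 0.55)      # cos(polar); cap opens the mouth
    th <- stats::runif(n_shell, 0, 2 * pi)
    rr <- 6 + stats::rnorm(n_shell, 0, 0.35)
    sh <- data.frame(
      element = "C",
      x = rr * sqrt(1 - u^2) * cos(th),
      y = rr * sqrt(1 - u^2) * sin(th),
      z = rr * u,
      radius = rep(c(1.9, 1.5), length.out = n_shell),
      charge = 0,
      atom_name = rep(c("CA", "CB"), length.out = n_shell),
      resname = "GLY",
      resno = 4L + seq_len(n_shell),
      chain = "A", stringsAsFactors = FALSE)
    receptor <- receptor_model(rbind(core, sh))
    # lipid slab: two planes, 8 A raster, hole over the +z pocket mouth only
    g <- expand.grid(x = seq(-24, 24, by = 8), y = seq(-24, 24, by = 8))
    top <- cbind(g$x, g$y, rep(slab_z / 2, nrow(g)))
    bot <- cbind(g$x, g$y, rep(-slab_z / 2, nrow(g)))
    mouth <- sqrt(top[, 1]^2 + top[, 2]^2) < 10   # exclude over the mouth
    lipid <- rbind(top[!mouth, , drop = FALSE], bot)
    colnames(lipid) <- c("x", "y", "z")
    # reference ligand: a compact cluster filling the pocket
    ref <- rbind(c(0, 0, -3.0), c(1.4, 0, -2.2), c(-1.2, 0.6, -2.1),
                 c(0.4, -1.2, -1.6), c(0.1, 1.1, -1.2), c(-0.4, -0.4, -0.2))
    colnames(ref) <- c("x", "y", "z")
    structure(list(receptor = receptor, lipid_atoms = lipid,
                   pocket_center = c(0, 0, -2), reference_ligand_atoms = ref,
                   slab_z = slab_z, seed = seed),
              class = "toy_complex")
  })
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("toy complex: %d receptor atoms, %d lipid points (slab %.1f A), %d reference atoms\n",
              nrow(x$receptor), nrow(x$lipid_atoms), x$slab_z,
              nrow(x$reference_ligand_atoms)))
  invisible(x)
}

#' Toy ligand conformer matched to a toy complex
#'
#' Returns a rigid \code{\link{ligand_conformer}} whose heavy atoms copy the
#' complex's reference-ligand geometry (so triplet matching against the
#' matching spheres always succeeds), carrying a single formal charge on the
#' first atom. Use \code{net_charge = -1} for a monoanion probe and
#' \code{+1} for its charge-inverted twin; geometry, vdW coefficients and
#' desolvation penalties are identical between the pair, isolating the
#' electrostatic term.
#'
#' @param complex a \code{\link{make_toy_complex}} result.
#' @param net_charge formal charge placed on the first (head) atom.
#' @param desolv per-atom desolvation penalty magnitude, kcal/mol.
#' @return A \code{ligand_conformer}.
#' @export
make_toy_ligand <- function(complex, net_charge = -1, desolv = 0.4) {
  ref <- complex$reference_ligand_atoms
  n <- nrow(ref)
  vp <- default_vdw_params()
  cc <- vp[vp$element == "C", ]
  atoms <- data.frame(
    element = rep("C", n), x = ref[, 1], y = ref[, 2], z = ref[, 3],
    charge = c(net_charge, rep(0, n - 1)),
    desolv = c(desolv, rep(desolv / 4, n - 1)),
    sqrtA = sqrt(cc$A), sqrtB = sqrt(cc$B), stringsAsFactors = FALSE)
  bonds <- cbind(seq_len(n - 1), 2:n)
  ligand_conformer(atoms, bonds, id = sprintf("toy_q%+d", net_charge))
}

#' Synthetic compound library specification
#'
#' @param n_total number of molecules (> 0).
#' @param fraction_carboxylate,fraction_bioisostere,fraction_neutral,fraction_cation
#'   class proportions; must be non-negative and sum to 1.
#' @param mwt_range molecular-weight window (amu) the drawn molecules must
#'   occupy (default the lead-like anion window 250-400).
#' @param seed integer seed.
#' @return Object of class \code{library_spec}.
#' @export
synthetic_library_spec <- function(n_total,
                                   fraction_carboxylate = 0.5,
                                   fraction_bioisostere = 0.2,
                                   fraction_neutral = 0.2,
                                   fraction_cation = 0.1,
                                   mwt_range = c(250, 400), seed = 1L) {
  fr <- c(carboxylate = fraction_carboxylate, bioisostere = fraction_bioisostere,
          neutral = fraction_neutral, cation = fraction_cation)
  if (!is.numeric(n_total) || n_total <= 0)
    stop("n_total must be positive")
  if (any(fr < 0)) stop("class fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("class fractions must sum to 1")
  if (length(mwt_range) != 2L || mwt_range[1] > mwt_range[2])
    stop("mwt_range must be an ordered interval")
  structure(list(n_total = as.integer(n_total), fractions = fr,
                 mwt_range = as.numeric(mwt_range), seed = seed),
            class = "library_spec")
}

# Curated SMILES templates per class; "{R}" is the decoration slot. The
# carboxylate templates all contain a neutral carboxylic acid, bioisostere
# templates a tetrazole / acylsulfonamide / hydroxamic acid and no
# carboxylic acid, neutrals carry no acidic or basic group, and cations an
# aliphatic amine. This gives exact pattern-match ground truth downstream.
library_templates <- function() {
  list(
    carboxylate = c(
      "OC(=O)c1ccc({R})cc1Oc1ccccc1",
      "OC(=O)Cc1ccc(Oc2ccc({R})cc2)cc1",
      "OC(=O)C1CCC(NC(=O)c2ccc({R})cc2)CC1",
      "OC(=O)c1ccc(CN(C(=O)c2ccccc2)C)cc1{R}"),
    bioisostere = c(
      "c1ccc(-c2nnn[nH]2)cc1Oc1ccc({R})cc1",
      "CS(=O)(=O)NC(=O)c1ccc({R})cc1Oc1ccccc1",
      "ONC(=O)c1ccc({R})cc1Cc1ccccc1",
      "c1ccc(Cc2ccc({R})cc2)cc1-c1nnn[nH]1"),
    neutral = c(
      "COc1ccc(C(=O)Nc2ccc({R})cc2)cc1OC",
      "O=C(N1CCOCC1)c1ccc(Oc2ccccn2)cc1{R}",
      "COc1ccc(Cc2ccc({R})cc2)cc1Oc1ccccc1"),
    cation = c(
      "NCCc1ccc({R})cc1Oc1ccccc1",
      "CN(C)CCOc1ccc({R})cc1Cc1ccccc1"))
}

library_decorations <- function() {
  c("Cl", "F", "Br", "C", "CC", "OC", "C(F)(F)F", "CCC", "OCC", "C#N")
}

#' Generate a compound library with known class composition
#'
#' Molecules are drawn from curated decorated SMILES templates per class
#' (carboxylates, carboxylate bioisosteres, neutral heteroaromatics,
#' aliphatic amines); class counts follow the requested fractions by
#' deterministic largest-remainder rounding, and only template variants whose
#' molecular weight falls inside \code{mwt_range} are drawn.
#'
#' @param spec a \code{\link{synthetic_library_spec}}.
#' @return data.frame with columns \code{id}, \code{smiles}, \code{class}.
#' @export
make_compound_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  counts <- largest_remainder(spec$n_total, spec$fractions)
  tpl <- library_templates()
  decs <- library_decorations()
  with_seed(spec$seed, {
    rows <- lapply(names(tpl), function(cls) {
      k <- counts[[cls]]
      if (k == 0) return(NULL)
      variants <- as.vector(vapply(tpl[[cls]], function(t)
        vapply(decs, function(d) gsub("{R}", d, t, fixed = TRUE),
               character(1)), character(length(decs))))
      mw <- smiles_mwt(variants)
      ok <- variants[mw >= spec$mwt_range[1] & mw <= spec$mwt_range[2]]
      if (length(ok) == 0)
        stop("no ", cls, " template variant falls inside mwt_range")
      data.frame(smiles = sample(ok, k, replace = TRUE), class = cls,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$id <- sprintf("CPD%05d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, c("id", "smiles", "class")]
  })
}

#' Planted-enrichment benchmark scores
#'
#' Draws decoy docking scores from N(0, 1) and ligand scores from
#' N(-score_gap, 1) (lower is better), keeping the labels — a synthetic
#' stand-in for a known-ligand versus property-matched-decoy control with a
#' controllable separation. \code{score_gap = Inf} gives complete separation.
#'
#' @param n_ligands,n_decoys positive counts.
#' @param score_gap mean score separation in score units (>= 0, may be Inf).
#' @param seed integer seed.
#' @return data.frame with columns \code{id}, \code{score},
#'   \code{is_ligand}.
#' @export
make_planted_benchmark <- function(n_ligands, n_decoys, score_gap, seed = 1L) {
  if (n_ligands <= 0 || n_decoys <= 0) stop("counts must be positive")
  if (score_gap < 0) stop("score_gap must be non-negative")
  with_seed(seed, {
    dec <- stats::rnorm(n_decoys, 0, 1)
    lig <- if (is.infinite(score_gap))
      min(dec) - 1 - abs(stats::rnorm(n_ligands, 0, 1))
    else stats::rnorm(n_ligands, -score_gap, 1)
    data.frame(
      id = c(sprintf("LIG%04d", seq_len(n_ligands)),
             sprintf("DEC%04d", seq_len(n_decoys))),
      score = c(lig, dec),
      is_ligand = rep(c(TRUE, FALSE), c(n_ligands, n_decoys)),
      stringsAsFactors = FALSE)
  })
}

#' Synthetic four-parameter logistic dose-response data
#'
#' Responses follow
#' \code{bottom + (top - bottom) / (1 + 10^((log10 c - log10 IC50) * hill))}
#' (an inhibition curve: response tends to \code{top} as the concentration
#' tends to zero) plus Gaussian noise.
#'
#' @param true_ic50 IC50 in molar (> 0).
#' @param hill Hill slope.
#' @param top,bottom asymptotes, percent of control.
#' @param concentrations strictly increasing positive molar concentrations.
#' @param noise_sd Gaussian noise SD in percent of control (0 = exact curve).
#' @param n_replicates technical replicates per concentration (default 3,
#'   the usual plate format).
#' @param seed integer seed.
#' @return Object of class \code{dose_response}: data.frame
#'   (\code{concentration}, \code{response}, \code{replicate}) with the
#'   generating parameters as attributes.
#' @export
make_dose_response <- function(true_ic50, hill = 1, top = 100, bottom = 0,
                               concentrations = 10^seq(-10, -5, by = 0.5),
                               noise_sd = 0, n_replicates = 3L, seed = 1L) {
  if (true_ic50 <= 0) stop("true_ic50 must be positive")
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be positive and strictly increasing")
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  conc <- rep(concentrations, each = n_replicates)
  y <- four_pl(conc, log10(true_ic50), hill, top, bottom)
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  structure(data.frame(concentration = conc, response = y,
                       replicate = rep(seq_len(n_replicates),
                                       times = length(concentrations))),
            class = c("dose_response", "data.frame"),
            true_ic50 = true_ic50, hill = hill, top = top, bottom = bottom,
            noise_sd = noise_sd, n_replicates = n_replicates, seed = seed)
}

# inhibition-convention 4PL
four_pl <- function(conc, log_ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^((log10(conc) - log_ic50) * hill))
}

#' Synthetic one-compartment pharmacokinetic profile
#'
#' Intravenous bolus: \code{C(t) = dose / Vd * exp(-ke t)}; oral or
#' intraperitoneal (first-order absorption, Bateman):
#' \code{C(t) = F ka dose / (Vd (ka - ke)) (exp(-ke t) - exp(-ka t))}.
#' Doses in mg/kg and Vd in ml/kg give mg/ml, reported as ng/ml (x 1e6).
#' Concentrations below \code{lloq} are censored: the numeric value is
#' withheld and the censoring flag set.
#'
#' @param dose dose, mg/kg.
#' @param route one of \code{"iv"}, \code{"oral"}, \code{"ip"}.
#' @param ka absorption rate constant, 1/min (oral/ip; must differ from
#'   \code{ke}).
#' @param ke elimination rate constant, 1/min.
#' @param Vd volume of distribution, ml/kg.
#' @param F_true absolute bioavailability fraction (oral/ip; iv is 1).
#' @param lloq lower limit of quantification, ng/ml.
#' @param timepoints sampling times, min (strictly increasing, >= 0).
#' @param noise_sd proportional Gaussian noise SD (0 = exact kinetics).
#' @param seed integer seed.
#' @return Object of class \code{pk_profile}: data.frame (\code{time},
#'   \code{conc}, \code{censored}) with dosing metadata as attributes;
#'   censored rows carry \code{NA} concentration.
#' @export
make_pk_profile <- function(dose, route = c("oral", "iv", "ip"), ka = 0.03,
                            ke = 0.005, Vd = 2000, F_true = 1, lloq = 10,
                            timepoints = c(5, 15, 30, 60, 120, 240, 360,
                                           480, 1440),
                            noise_sd = 0, seed = 1L) {
  route <- match.arg(route)
  if (dose <= 0 || ke <= 0 || Vd <= 0 || lloq < 0)
    stop("dose, ke, Vd must be positive and lloq non-negative")
  if (F_true < 0 || F_true > 1) stop("F_true must be a fraction in [0, 1]")
  if (is.unsorted(timepoints, strictly = TRUE) || any(timepoints < 0))
    stop("timepoints must be non-negative and strictly increasing")
  t <- timepoints
  c_ngml <- if (route == "iv") {
    dose * 1e6 / Vd * exp(-ke * t)
  } else {
    if (ka <= 0) stop("ka must be positive")
    if (ka == ke)
      stop("ka must differ from ke for extravascular routes (degenerate Bateman form)")
    F_true * dose * 1e6 * ka / (Vd * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  }
  if (noise_sd > 0)
    c_ngml <- with_seed(seed, pmax(0, c_ngml *
                                     (1 + stats::rnorm(length(t), 0, noise_sd))))
  censored <- c_ngml < lloq
  structure(data.frame(time = t,
                       conc = ifelse(censored, NA_real_, c_ngml),
                       censored = censored),
            class = c("pk_profile", "data.frame"),
            dose = dose, route = route, lloq = lloq,
            ka = if (route == "iv") NA_real_ else ka, ke = ke, Vd = Vd,
            F_true = if (route == "iv") 1 else F_true)
}
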