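# Small-molecule utilities on top of ChemmineR/ChemmineOB (OpenBabel):
# SMILES parsing, molecular graphs, formal charges, circular fingerprints
# and Tanimoto similarity. SDF molecules from OpenBabel are kekulized with
# implicit hydrogens, so graphs here contain heavy atoms only.

#' Parse SMILES into an SDFset
#'
#' Wraps \code{ChemmineR::smiles2sdf} with per-molecule error recovery:
#' unparseable SMILES are dropped and reported rather than aborting the
#' batch.
#'
#' @param smiles character vector of SMILES.
#' @param ids molecule identifiers (default names or index-based).
#' @return list with \code{sdf} (an \code{SDFset} of the valid molecules),
#'   \code{valid} (logical vector aligned with the input) and
#'   \code{rejected} (ids of dropped molecules).
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles) %||% sprintf("mol%04d", seq_along(smiles))
  names(smiles) <- ids
  parse_one <- function(s, id) {
    out <- try(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, id))),
               silent = TRUE)
    if (inherits(out, "try-error") || length(out) != 1L) return(NULL)
    if (nrow(ChemmineR::atomblock(out[[1]])) < 1L) return(NULL)
    out
  }
  batch <- try(suppressWarnings(ChemmineR::smiles2sdf(smiles)), silent = TRUE)
  if (!inherits(batch, "try-error") && length(batch) == length(smiles)) {
    return(list(sdf = batch, valid = rep(TRUE, length(smiles)),
                rejected = character(0)))
  }
  parsed <- lapply(seq_along(smiles), function(i) parse_one(smiles[i], ids[i]))
  valid <- !vapply(parsed, is.null, logical(1))
  if (!any(valid)) stop("no valid SMILES in input")
  sdf <- Reduce(function(a, b) c(a, b), parsed[valid])
  list(sdf = sdf, valid = valid, rejected = ids[!valid])
}

# one OpenBabel molecule handle per SMILES (robust to single-atom species,
# where the SDF round-trip degenerates)
ob_mols <- function(smiles) {
  lapply(smiles, function(s) {
    m <- try(suppressWarnings(
      ChemmineOB::forEachMol("SMILES", s, identity)), silent = TRUE)
    if (inherits(m, "try-error")) stop("unparseable SMILES: ", s)
    m
  })
}

ob_props <- function(smiles) {
  do.call(rbind, lapply(ob_mols(smiles), ChemmineOB::prop_OB))
}

#' Molecular weights of SMILES
#' @param smiles character vector (all must parse).
#' @return numeric vector of average-isotope molecular weights, amu.
#' @export
smiles_mwt <- function(smiles) {
  ob_props(smiles)$MW
}

#' Canonical SMILES
#' @param smiles character vector (all must parse).
#' @return canonical SMILES (OpenBabel canonicalisation, no stereo).
#' @export
canonical_smiles <- function(smiles) {
  unname(ob_props(smiles)$cansmiNS)
}

# SDF legacy charge field <-> formal charge (code 4 is a radical, not used)
charge_code_to_formal <- function(code) ifelse(code %in% 1:7 & code != 4,
                                               4 - code, 0)
formal_to_charge_code <- function(q) ifelse(q == 0, 0, 4 - q)

# heavy-atom molecular graph straight from SMILES: OpenBabel emits the
# kekulized V2000 block, parsed here by fixed-width fields (robust down to
# single-atom molecules, where the SDFset route degenerates)
mol_graph_from_smiles <- function(smiles) {
  txt <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles)), silent = TRUE)
  if (inherits(txt, "try-error") || !nzchar(txt))
    stop("unparseable SMILES: ", smiles)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  natoms <- as.integer(substr(lines[4], 1, 3))
  nbonds <- as.integer(substr(lines[4], 4, 6))
  if (is.na(natoms) || natoms < 1) stop("unparseable SMILES: ", smiles)
  at <- lines[4 + seq_len(natoms)]
  atoms <- data.frame(
    element = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    formal_charge = charge_code_to_formal(as.integer(substr(at, 37, 39))),
    stringsAsFactors = FALSE)
  bonds <- if (nbonds > 0) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    data.frame(a1 = as.integer(substr(bl, 1, 3)),
               a2 = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  # M CHG lines override the legacy atom-line codes
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    atoms$formal_charge <- 0
    for (ln in chg) {
      n <- as.integer(substr(ln, 7, 9))
      for (k in seq_len(n)) {
        off <- 10 + (k - 1) * 8
        ai <- as.integer(substr(ln, off, off + 3))
        atoms$formal_charge[ai] <- as.integer(substr(ln, off + 4, off + 7))
      }
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# heavy-atom molecular graph of one SDF molecule
mol_graph <- function(mol) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  element <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(
    element = element,
    x = ab[, "C1"], y = ab[, "C2"], z = ab[, "C3"],
    formal_charge = charge_code_to_formal(ab[, "C6"]),
    stringsAsFactors = FALSE)
  bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3)
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  else data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  bonds <- bonds[bonds$a1 > 0 & bonds$a2 > 0, , drop = FALSE]
  rownames(atoms) <- NULL
  list(atoms = atoms, bonds = bonds)
}

# neighbour index list of a molecular graph
graph_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# a bond is a ring bond iff its endpoints stay connected after removing it
ring_bond_flags <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  adj <- graph_adjacency(g)
  vapply(seq_len(nb), function(b) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    # BFS from i to j avoiding the direct edge
    seen <- rep(FALSE, nrow(g$atoms))
    seen[i] <- TRUE
    queue <- setdiff(adj[[i]], j)
    # careful: parallel paths through other bonds only
    queue <- queue[!seen[queue]]
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == j) return(TRUE)
      nxt <- adj[[v]][!seen[adj[[v]]]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    FALSE
  }, logical(1))
}

# rotatable bond: acyclic single bond between two heavy atoms of degree >= 2,
# excluding amide C-N bonds (the conventional rotor count)
rotatable_bond_flags <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  deg <- tabulate(c(g$bonds$a1, g$bonds$a2), nbins = nrow(g$atoms))
  ring <- ring_bond_flags(g)
  adj <- graph_adjacency(g)
  is_amide <- function(ci, ni) {
    g$atoms$element[ci] == "C" && g$atoms$element[ni] == "N" &&
      any(vapply(adj[[ci]], function(k) {
        g$atoms$element[k] == "O" &&
          any(g$bonds$order[(g$bonds$a1 == ci & g$bonds$a2 == k) |
                              (g$bonds$a2 == ci & g$bonds$a1 == k)] == 2)
      }, logical(1)))
  }
  vapply(seq_len(nb), function(b) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    if (g$bonds$order[b] != 1L || ring[b]) return(FALSE)
    if (deg[i] < 2L || deg[j] < 2L) return(FALSE)
    if (is_amide(i, j) || is_amide(j, i)) return(FALSE)
    TRUE
  }, logical(1))
}

count_rotatable_bonds <- function(g) sum(rotatable_bond_flags(g))

# dihedrals examined by the strain model: like rotors but amide bonds are
# kept (their cis/trans strain is exactly what the rule table penalises)
strain_bond_flags <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  deg <- tabulate(c(g$bonds$a1, g$bonds$a2), nbins = nrow(g$atoms))
  ring <- ring_bond_flags(g)
  vapply(seq_len(nb), function(b) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    g$bonds$order[b] == 1L && !ring[b] && deg[i] >= 2L && deg[j] >= 2L
  }, logical(1))
}

#' Circular (ECFP4-style) fingerprints
#'
#' Radius-2 extended-connectivity fingerprints from OpenBabel, folded by OR
#' to 2048 bits — the carrier of all Tanimoto comparisons in clustering,
#' novelty filtering and decoy selection.
#'
#' @param sdf an \code{SDFset} or character SMILES vector.
#' @return logical matrix, one row per molecule, 2048 columns.
#' @export
ecfp_fingerprints <- function(sdf) {
  smiles <- if (is.character(sdf)) sdf
  else as.character(ChemmineR::sdf2smiles(sdf))
  raw <- lapply(ob_mols(smiles), function(m)
    as.numeric(ChemmineOB::fingerprint_OB(m, "ECFP4")))
  fp <- do.call(rbind, raw)
  half <- ncol(fp) / 2
  folded <- (fp[, seq_len(half), drop = FALSE] +
               fp[, half + seq_len(half), drop = FALSE]) > 0
  rownames(folded) <- names(smiles) %||%
    (if (is.character(sdf)) NULL else ChemmineR::sdfid(sdf))
  folded
}

#' Tanimoto coefficient between two bit vectors
#'
#' @param a,b logical fingerprint vectors of equal length.
#' @return Tc = |a AND b| / |a OR b|; two empty sets have Tc 1.
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# all-pairs Tanimoto between rows of two fingerprint matrices
tanimoto_cross <- function(fpA, fpB) {
  A <- matrix(as.numeric(fpA), nrow = nrow(fpA))
  B <- matrix(as.numeric(fpB), nrow = nrow(fpB))
  inter <- A %*% t(B)
  na <- rowSums(A); nb <- rowSums(B)
  un <- outer(na, nb, "+") - inter
  tc <- ifelse(un == 0, 1, inter / un)
  tc
}
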