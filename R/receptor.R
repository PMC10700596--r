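#' Construct a receptor model
#'
#' A receptor model is the atom-level description of the target used for grid
#' generation: Cartesian coordinates in Angstrom, per-atom radii and partial
#' charges (elementary charge units), and PDB-style residue bookkeeping.
#'
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{radius} (Angstrom, > 0), \code{charge} (e),
#'   \code{atom_name}, \code{resname}, \code{resno} (1-based), \code{chain}.
#' @return An object of class \code{receptor_model}: the atom table with a
#'   \code{net_charge} attribute equal to the sum of partial charges.
#' @examples
#' rec <- receptor_model(data.frame(
#'   element = c("N", "C"), x = c(0, 1.4), y = 0, z = 0,
#'   radius = 1.65, charge = c(-0.4, 0.4), atom_name = c("N", "CA"),
#'   resname = "ALA", resno = 1, chain = "A"))
#' net_charge(rec)
#' @export
receptor_model <- function(atoms) {
  required <- c("element", "x", "y", "z", "radius", "charge",
                "atom_name", "resname", "resno", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("receptor atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("receptor must contain at least one atom")
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0))
    stop("atom radii must be positive and finite")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  atoms <- as.data.frame(atoms)[, required]
  structure(atoms, class = c("receptor_model", "data.frame"),
            net_charge = sum(atoms$charge))
}

#' @export
net_charge <- function(x) UseMethod("net_charge")

#' @export
net_charge.receptor_model <- function(x) sum(x$charge)

#' @export
print.receptor_model <- function(x, ...) {
  cat(sprintf("receptor model: %d atoms, %d residues, net charge %+.3f e\n",
              nrow(x), length(unique(paste(x$chain, x$resno))), net_charge(x)))
  invisible(x)
}

receptor_coords <- function(receptor) {
  as.matrix(receptor[, c("x", "y", "z")])
}

#' Regular lattice specification for scoring grids
#'
#' @param origin numeric length-3, coordinates (Angstrom) of the first lattice
#'   node.
#' @param spacing scalar node spacing in Angstrom.
#' @param dims integer length-3, number of nodes along x, y, z (>= 2 each).
#' @return Object of class \code{lattice_spec}.
#' @export
lattice_spec <- function(origin, spacing, dims) {
  origin <- as.numeric(origin); dims <- as.integer(dims)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  if (length(dims) != 3L || any(dims < 2L)) stop("dims must be 3 integers >= 2")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("lattice: %d x %d x %d nodes, spacing %.3f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Lattice covering a receptor with a margin on every side
#'
#' @param receptor a \code{receptor_model}.
#' @param spacing node spacing, Angstrom (default 0.4).
#' @param margin clearance beyond the atom bounding box, Angstrom (default 6).
#' @return A \code{lattice_spec}.
#' @export
lattice_around <- function(receptor, spacing = 0.4, margin = 6) {
  xyz <- receptor_coords(receptor)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  lattice_spec(lo, spacing, dims)
}

# node coordinates along each axis
lattice_axes <- function(lat) {
  lapply(1:3, function(k) lat$origin[k] + lat$spacing * (seq_len(lat$dims[k]) - 1))
}

lattice_max <- function(lat) lat$origin + lat$spacing * (lat$dims - 1)

lattice_covers <- function(lat, xyz, clearance = 0) {
  lo <- lat$origin + clearance
  hi <- lattice_max(lat) - clearance
  all(sweep(xyz, 2, lo, ">=")) && all(sweep(xyz, 2, hi, "<="))
}

same_lattice <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) && abs(a$spacing - b$spacing) < tol &&
    all(a$dims == b$dims)
}

#' Read a receptor from PDB with charges and radii from a parameter table
#'
#' ATOM and HETATM records are read with \pkg{bio3d}; occupancy and B-factor
#' are ignored. Charges and radii come from a whitespace-delimited parameter
#' table with columns \code{resname}, \code{atom_name}, \code{charge},
#' \code{radius}; a row with \code{resname == "*"} acts as an element-level
#' fallback keyed by \code{atom_name}.
#'
#' Records with residue name \code{lipid_resname} (HETATM lipid points) are
#' split off and returned as the \code{lipid_atoms} attribute — lipid atoms
#' carry no charges and take no parameters.
#'
#' @param pdb_file path to a PDB file.
#' @param param_file path to the charge/radius table.
#' @param lipid_resname residue name marking lipid points (default "LIP").
#' @return A \code{receptor_model}; lipid coordinates, if any, in
#'   \code{attr(, "lipid_atoms")}.
#' @export
read_receptor_pdb <- function(pdb_file, param_file, lipid_resname = "LIP") {
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  lip <- at[at$resid == lipid_resname, c("x", "y", "z")]
  at <- at[at$resid != lipid_resname, ]
  pars <- utils::read.table(param_file, header = TRUE,
                            stringsAsFactors = FALSE)
  key <- paste(at$resid, at$elety)
  idx <- match(key, paste(pars$resname, pars$atom_name))
  fb <- match(paste("*", at$elesy), paste(pars$resname, pars$atom_name))
  idx[is.na(idx)] <- fb[is.na(idx)]
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no charge/radius parameters for: ", paste(bad, collapse = "; "))
  }
  rec <- receptor_model(data.frame(
    element = at$elesy, x = at$x, y = at$y, z = at$z,
    radius = pars$radius[idx], charge = pars$charge[idx],
    atom_name = at$elety, resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE))
  if (nrow(lip) > 0) attr(rec, "lipid_atoms") <- as.matrix(lip)
  rec
}

#' Charge/radius parameter table of a receptor
#'
#' Collapses a receptor's atoms to the unique (resname, atom_name) keys with
#' their charge and radius, the table format \code{\link{read_receptor_pdb}}
#' consumes. Fails if a key maps to more than one (charge, radius) pair.
#'
#' @param receptor a \code{\link{receptor_model}}.
#' @param file optional path; when given the table is written
#'   whitespace-delimited with a header.
#' @return data.frame with columns \code{resname}, \code{atom_name},
#'   \code{charge}, \code{radius}.
#' @export
receptor_param_table <- function(receptor, file = NULL) {
  tab <- unique(data.frame(resname = receptor$resname,
                           atom_name = receptor$atom_name,
                           charge = receptor$charge,
                           radius = receptor$radius,
                           stringsAsFactors = FALSE))
  key <- paste(tab$resname, tab$atom_name)
  if (anyDuplicated(key))
    stop("inconsistent parameters for key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(file))
    utils::write.table(tab, file, row.names = FALSE, quote = FALSE)
  tab
}

#' Write a receptor (and optionally lipid points) to PDB
#'
#' Lipid points are written as HETATM carbons with residue name \code{LIP}.
#'
#' @param receptor a \code{receptor_model}.
#' @param file output path.
#' @param lipid_atoms optional n x 3 matrix of lipid apolar-atom coordinates.
#' @return \code{file}, invisibly.
#' @export
write_receptor_pdb <- function(receptor, file, lipid_atoms = NULL) {
  n <- nrow(receptor)
  xyz <- as.vector(t(receptor_coords(receptor)))
  resno <- receptor$resno
  typ <- rep("ATOM", n)
  elety <- receptor$atom_name
  resid <- receptor$resname
  chain <- receptor$chain
  if (!is.null(lipid_atoms) && nrow(lipid_atoms) > 0) {
    m <- nrow(lipid_atoms)
    xyz <- c(xyz, as.vector(t(lipid_atoms)))
    typ <- c(typ, rep("HETATM", m))
    elety <- c(elety, rep("C1", m))
    resid <- c(resid, rep("LIP", m))
    chain <- c(chain, rep("L", m))
    resno <- c(resno, max(resno) + seq_len(m))
  }
  bio3d::write.pdb(file = file, type = typ, xyz = xyz, resno = resno,
                   resid = resid, eleno = seq_along(typ), elety = elety,
                   chain = chain)
  invisible(file)
}
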