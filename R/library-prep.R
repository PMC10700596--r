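# Anion library construction: SMARTS harvesting of carboxylates and their
# bioisosteres, rule-based pH-7 protonation, property computation, lead-like
# filtering and building-block analog enumeration.

#' Default carboxylate/bioisostere pattern table
#'
#' A curated stand-in for the full bioisostere SMARTS collection: the
#' carboxylic acid itself plus common acidic bioisosteres (tetrazole,
#' acylsulfonamide, hydroxamic, sulfonic, sulfinic and phosphonic acids).
#' Fully overridable: supply any table with columns \code{id},
#' \code{smarts}, \code{class} to the harvesting functions, or load one from
#' TSV with \code{\link{read_pattern_table}}.
#'
#' @return data.frame with columns \code{id}, \code{smarts}, \code{class}
#'   (\code{"carboxylate"} or \code{"bioisostere"}).
#' @export
default_pattern_table <- function() {
  data.frame(
    id = c("carboxylic_acid", "tetrazole", "tetrazolide", "acylsulfonamide",
           "hydroxamic_acid", "sulfonic_acid", "sulfinic_acid",
           "phosphonic_acid"),
    smarts = c("[CX3](=O)[OX2H1,OX1-]",
               "c1nnn[nH]1",
               "c1nnn[n-]1",
               "[CX3](=O)[NX3H1,NX3-][SX4](=O)(=O)",
               "[CX3](=O)[NX3H1][OX2H1]",
               "[SX4](=O)(=O)[OX2H1,OX1-]",
               "[SX3](=O)[OX2H1,OX1-]",
               "[PX4](=O)([OX2H1,OX1-])"),
    class = c("carboxylate", rep("bioisostere", 7)),
    stringsAsFactors = FALSE)
}

#' Read a pattern table from TSV
#' @param file TSV with header columns \code{id}, \code{smarts},
#'   \code{class}.
#' @return validated pattern table.
#' @export
read_pattern_table <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  validate_pattern_table(tab)
}

validate_pattern_table <- function(tab) {
  if (!all(c("id", "smarts", "class") %in% names(tab)))
    stop("pattern table needs columns id, smarts, class")
  if (anyDuplicated(tab$id)) stop("pattern ids must be unique")
  tab
}

#' Harvest acids by substructure pattern
#'
#' Retains every molecule matching at least one pattern of the table,
#' recording which patterns matched. Unparseable SMILES are logged, skipped
#' and tallied.
#'
#' @param smiles character vector of SMILES (names used as ids).
#' @param patterns a pattern table (default
#'   \code{\link{default_pattern_table}}).
#' @return list with \code{records} (data.frame id, smiles,
#'   \code{matched_patterns} list-column, \code{class} of the first matched
#'   pattern), \code{class_counts}, \code{n_rejected_parse} and the rejected
#'   ids.
#' @export
harvest_acids <- function(smiles, patterns = default_pattern_table()) {
  patterns <- validate_pattern_table(patterns)
  p <- parse_smiles(smiles)
  ids <- names(smiles) %||% sprintf("mol%04d", seq_along(smiles))
  kept_ids <- ids[p$valid]
  hits <- matrix(FALSE, nrow = length(p$sdf), ncol = nrow(patterns),
                 dimnames = list(NULL, patterns$id))
  for (k in seq_len(nrow(patterns))) {
    cnt <- ChemmineR::smartsSearchOB(p$sdf, patterns$smarts[k],
                                     uniqueMatches = FALSE)
    hits[, k] <- cnt > 0
  }
  any_hit <- rowSums(hits) > 0
  matched <- lapply(which(any_hit), function(i) patterns$id[hits[i, ]])
  cls <- vapply(which(any_hit),
                function(i) patterns$class[which(hits[i, ])[1]], character(1))
  records <- data.frame(id = kept_ids[any_hit],
                        smiles = as.character(smiles[p$valid][any_hit]),
                        class = cls, stringsAsFactors = FALSE)
  records$matched_patterns <- I(matched)
  list(records = records,
       class_counts = table(factor(cls, levels = unique(patterns$class))),
       n_rejected_parse = length(p$rejected), rejected = p$rejected)
}

# ---- protonation rule engine ---------------------------------------------
# Group finders operate on the kekulized heavy-atom graph and return atom
# indices to (de)protonate with the charge delta. Rules never fire on atoms
# that already carry a formal charge, which makes the engine idempotent.

find_cycles <- function(g, max_len = 7L) {
  adj <- graph_adjacency(g)
  n <- nrow(g$atoms)
  cycles <- list()
  seen <- character(0)
  path <- integer(0)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    for (w in adj[[v]]) {
      if (w == start && depth >= 3L) {
        cyc <- sort(path[seq_len(depth)])
        key <- paste(cyc, collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- path[seq_len(depth)]
        }
      } else if (depth < max_len && !(w %in% path[seq_len(depth)]) &&
                 w > start) {
        dfs(start, w, depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) dfs(s, s, 1L)
  cycles
}

bond_order_between <- function(g, i, j) {
  hit <- (g$bonds$a1 == i & g$bonds$a2 == j) |
    (g$bonds$a1 == j & g$bonds$a2 == i)
  if (!any(hit)) 0L else g$bonds$order[which(hit)[1]]
}

# carboxylic, sulfonic, sulfinic, phosphonic: acidic OH on a C/S/P centre
# that also carries a double-bonded O -> deprotonate the OH oxygen
find_acidic_hydroxyls <- function(g) {
  adj <- graph_adjacency(g)
  deg <- lengths(adj)
  out <- integer(0)
  for (c0 in which(g$atoms$element %in% c("C", "S", "P"))) {
    nb <- adj[[c0]]
    dbl_o <- nb[g$atoms$element[nb] == "O" &
                  vapply(nb, function(k) bond_order_between(g, c0, k) == 2L,
                         logical(1))]
    if (length(dbl_o) == 0) next
    # idempotence: a centre that already lost one proton never loses another
    if (any(g$atoms$element[nb] == "O" & g$atoms$formal_charge[nb] < 0)) next
    oh <- nb[g$atoms$element[nb] == "O" & deg[nb] == 1L &
               g$atoms$formal_charge[nb] == 0 &
               vapply(nb, function(k) bond_order_between(g, c0, k) == 1L,
                      logical(1))]
    if (length(oh)) out <- c(out, oh[1])  # one proton per acidic centre
  }
  unique(out)
}

# tetrazole NH: a neutral all-single-bond N inside a 5-ring with >= 3
# nitrogens (the pyrrole-type position of a kekulized tetrazole)
find_tetrazole_nh <- function(g) {
  rings <- find_cycles(g, max_len = 5L)
  out <- integer(0)
  for (r in rings) {
    if (length(r) != 5L) next
    if (sum(g$atoms$element[r] == "N") < 4L) next
    nh <- r[g$atoms$element[r] == "N" & g$atoms$formal_charge[r] == 0 &
              vapply(r, function(v) {
                nbr <- intersect(graph_adjacency(g)[[v]], r)
                all(vapply(nbr, function(w)
                  bond_order_between(g, v, w) == 1L, logical(1)))
              }, logical(1))]
    if (length(nh)) out <- c(out, nh[1])
  }
  unique(out)
}

# basic aliphatic amine: neutral N, all bonds single, every neighbour an sp3
# carbon (no neighbour with a multiple bond, which excludes amides, anilines,
# sulfonamides and imines)
find_basic_amines <- function(g) {
  adj <- graph_adjacency(g)
  has_multiple <- rep(FALSE, nrow(g$atoms))
  if (nrow(g$bonds)) {
    mb <- g$bonds[g$bonds$order > 1L, ]
    has_multiple[unique(c(mb$a1, mb$a2))] <- TRUE
  }
  out <- integer(0)
  for (n0 in which(g$atoms$element == "N")) {
    if (g$atoms$formal_charge[n0] != 0) next
    nb <- adj[[n0]]
    if (length(nb) == 0) next
    orders <- vapply(nb, function(k) bond_order_between(g, n0, k), integer(1))
    if (any(orders != 1L)) next
    if (!all(g$atoms$element[nb] == "C")) next
    if (any(has_multiple[nb])) next
    out <- c(out, n0)
  }
  out
}

# amidine / guanidine: N double-bonded to an acyclic carbon with >= 2 N
# neighbours and no O or S neighbours -> protonate that N (ring carbons are
# excluded so azole tautomers such as tetrazoles never match)
find_amidine_n <- function(g) {
  adj <- graph_adjacency(g)
  rb <- ring_bond_flags(g)
  in_ring <- rep(FALSE, nrow(g$atoms))
  if (any(rb)) in_ring[unique(c(g$bonds$a1[rb], g$bonds$a2[rb]))] <- TRUE
  out <- integer(0)
  for (c0 in which(g$atoms$element == "C" & !in_ring)) {
    nb <- adj[[c0]]
    if (sum(g$atoms$element[nb] == "N") < 2L) next
    if (any(g$atoms$element[nb] %in% c("O", "S"))) next
    ndbl <- nb[g$atoms$element[nb] == "N" & g$atoms$formal_charge[nb] == 0 &
                 vapply(nb, function(k) bond_order_between(g, c0, k) == 2L,
                        logical(1))]
    if (length(ndbl)) out <- c(out, ndbl[1])
  }
  unique(out)
}

#' Rule-based pH-7 protonation
#'
#' Applies a fixed transform table to each molecule: carboxylic, sulfonic,
#' sulfinic and phosphonic acid hydroxyls and tetrazole N-H are deprotonated
#' (-1 each); aliphatic amines and amidine/guanidine nitrogens are
#' protonated (+1 each). Molecules matching no rule pass through unchanged.
#' The rules are idempotent: a group that already carries a charge is never
#' transformed again.
#'
#' @param smiles character vector of neutral-form SMILES.
#' @return data.frame with columns \code{smiles_in}, \code{smiles} (charged
#'   form) and \code{net_charge} (sum of formal charges, e).
#' @export
assign_protonation <- function(smiles) {
  out_smiles <- character(length(smiles))
  out_q <- numeric(length(smiles))
  for (i in seq_along(smiles)) {
    g <- mol_graph_from_smiles(smiles[[i]])
    minus <- unique(c(find_acidic_hydroxyls(g), find_tetrazole_nh(g)))
    plus <- unique(c(find_basic_amines(g), find_amidine_n(g)))
    q <- g$atoms$formal_charge
    q[minus] <- q[minus] - 1L
    q[plus] <- q[plus] + 1L
    out_q[i] <- sum(q)
    if (length(minus) || length(plus)) {
      g$atoms$formal_charge <- q
      out_smiles[i] <- graph_to_smiles(g$atoms, g$bonds, id = "prot")
    } else {
      out_smiles[i] <- smiles[[i]]
    }
  }
  data.frame(smiles_in = as.character(smiles), smiles = out_smiles,
             net_charge = out_q, stringsAsFactors = FALSE)
}

#' Compute compound property records
#'
#' Annotates molecules with the descriptors the screening cascade consumes:
#' average-isotope molecular weight, atom-contribution clogP, net formal
#' charge, heavy atoms, rotatable bonds, hydrogen-bond donors/acceptors,
#' canonical SMILES and a 2048-bit radius-2 circular fingerprint.
#'
#' @param smiles character vector of SMILES (names used as ids).
#' @return data.frame with one row per molecule: \code{id}, \code{smiles},
#'   \code{cansmi}, \code{mwt}, \code{clogp}, \code{net_charge},
#'   \code{heavy_atoms}, \code{rotatable_bonds}, \code{hbd}, \code{hba} and
#'   a \code{fingerprint} list-column of set-bit indices.
#' @export
compute_properties <- function(smiles) {
  ids <- names(smiles) %||% sprintf("mol%04d", seq_along(smiles))
  props <- ob_props(smiles)
  fp <- ecfp_fingerprints(as.character(smiles))
  graphs <- lapply(smiles, mol_graph_from_smiles)
  rec <- data.frame(
    id = ids, smiles = as.character(smiles),
    cansmi = unname(props$cansmiNS),
    mwt = props$MW, clogp = props$logP,
    net_charge = vapply(graphs, function(g) sum(g$atoms$formal_charge),
                        numeric(1)),
    heavy_atoms = vapply(graphs, function(g) sum(g$atoms$element != "H"),
                         numeric(1)),
    rotatable_bonds = vapply(graphs, count_rotatable_bonds, numeric(1)),
    hbd = props$HBD, hba = props$HBA1,
    stringsAsFactors = FALSE)
  rec$fingerprint <- I(lapply(seq_len(nrow(fp)), function(i) which(fp[i, ])))
  rec
}

#' Lead-like property filter
#'
#' A record passes iff its molecular weight, clogP and net charge all fall
#' inside the stated windows; boundaries are inclusive. A charge of -2 in
#' \code{allowed_charges} stands for the open-ended "dianion or below"
#' bucket (any net charge <= -2 passes it).
#'
#' @param records a \code{\link{compute_properties}} data.frame.
#' @param mwt_range inclusive molecular-weight window, amu (default the
#'   anion-screen window 250-400).
#' @param clogp_range inclusive clogP window (default 1-5).
#' @param allowed_charges permitted net charges (default \code{c(-2, -1, 0)},
#'   i.e. anions and neutrals, cations excluded).
#' @return list with \code{records} (the passing subset) and
#'   \code{rejections}, the per-rule rejection counts (each rejected record
#'   is attributed to its first failing rule, in order mwt, clogp, charge,
#'   so the counts sum to the number rejected).
#' @export
filter_leadlike <- function(records, mwt_range = c(250, 400),
                            clogp_range = c(1, 5),
                            allowed_charges = c(-2, -1, 0)) {
  if (mwt_range[1] > mwt_range[2] || clogp_range[1] > clogp_range[2])
    stop("property ranges must be ordered")
  ok_mwt <- records$mwt >= mwt_range[1] & records$mwt <= mwt_range[2]
  ok_logp <- records$clogp >= clogp_range[1] & records$clogp <= clogp_range[2]
  ok_q <- records$net_charge %in% allowed_charges |
    (any(allowed_charges <= -2) & records$net_charge <= -2)
  pass <- ok_mwt & ok_logp & ok_q
  rejections <- c(mwt = sum(!ok_mwt),
                  clogp = sum(ok_mwt & !ok_logp),
                  charge = sum(ok_mwt & ok_logp & !ok_q))
  list(records = records[pass, , drop = FALSE], rejections = rejections)
}

#' Read and write whitespace-separated SMILES files
#'
#' The \code{.smi} convention: one molecule per line, SMILES then id,
#' whitespace-separated.
#'
#' @param file path.
#' @return \code{read_smi}: named character vector of SMILES (names are
#'   ids).
#' @export
read_smi <- function(file) {
  tab <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("smiles", "id"), fill = TRUE)
  tab$id[tab$id == ""] <- sprintf("mol%04d", which(tab$id == ""))
  stats::setNames(tab$smiles, tab$id)
}

#' @rdname read_smi
#' @param smiles named character vector of SMILES.
#' @export
write_smi <- function(smiles, file) {
  ids <- names(smiles) %||% sprintf("mol%04d", seq_along(smiles))
  writeLines(paste(smiles, ids), file)
  invisible(file)
}

# ---- building-block decomposition / analog enumeration --------------------

#' Amide reaction scheme
#'
#' The retro-transform cuts the C(=O)-N amide bond into an acid (the
#' carbonyl side, re-capped with OH) and an amine; the forward transform
#' condenses an acid and an amine back into the amide. Round-tripping a
#' product through retro then forward regenerates its canonical SMILES.
#'
#' @return Object of class \code{reaction_scheme}.
#' @export
amide_scheme <- function() {
  structure(list(id = "amide", roles = c("acid", "amine")),
            class = "reaction_scheme")
}

# amide bonds: single C-N where C bears a double-bonded O and, to exclude
# the acid itself, N is not an -OH-bearing oxygen path; returns bond rows
find_amide_bonds <- function(g) {
  adj <- graph_adjacency(g)
  hits <- list()
  for (b in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[b] != 1L) next
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    for (sw in 1:2) {
      ci <- if (sw == 1) i else j
      ni <- if (sw == 1) j else i
      if (g$atoms$element[ci] == "C" && g$atoms$element[ni] == "N") {
        dbl_o <- any(vapply(adj[[ci]], function(k)
          g$atoms$element[k] == "O" && bond_order_between(g, ci, k) == 2L,
          logical(1)))
        if (dbl_o) hits[[length(hits) + 1L]] <- c(C = ci, N = ni, bond = b)
      }
    }
  }
  hits
}

# connected component containing seed after dropping one bond
component_of <- function(g, seed, drop_bond) {
  adj_b <- g$bonds[-drop_bond, , drop = FALSE]
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(adj_b))) {
    i <- adj_b$a1[b]; j <- adj_b$a2[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n); seen[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- adj[[v]][!seen[adj[[v]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  which(seen)
}

# emit a (sub)graph as SMILES through an SDF round-trip
graph_to_smiles <- function(atoms, bonds, id = "frag") {
  n <- nrow(atoms)
  lines <- c(id, "  package generated", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  for (k in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
      atoms$x[k], atoms$y[k], atoms$z[k], atoms$element[k],
      formal_to_charge_code(atoms$formal_charge[k])))
  }
  for (b in seq_len(nrow(bonds))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds$a1[b], bonds$a2[b], bonds$order[b]))
  }
  chg <- which(atoms$formal_charge != 0)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg,
                                            atoms$formal_charge[chg]),
                                    collapse = "")))
  lines <- c(lines, "M  END", "$$$$")
  out <- ChemmineOB::convertFormat("SDF", "SMI",
                                   source = paste(lines, collapse = "\n"))
  strsplit(trimws(out), "[ \t]")[[1]][1]
}

subgraph_smiles <- function(g, keep, id = "frag") {
  idx <- match(seq_len(nrow(g$atoms)), keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- g$bonds$a1 %in% keep & g$bonds$a2 %in% keep
  bonds <- data.frame(a1 = idx[g$bonds$a1[bsel]], a2 = idx[g$bonds$a2[bsel]],
                      order = g$bonds$order[bsel])
  graph_to_smiles(atoms, bonds, id = id)
}

#' Decompose an amide product and enumerate analog products
#'
#' Retro-cuts the product's single amide bond into its acid and amine
#' building blocks, then re-couples every acid in \code{acid_pool} with
#' every amine in \code{amine_pool}, canonicalizing and deduplicating the
#' products. When the original fragments are present in the pools the
#' original product is regenerated among the analogs.
#'
#' @param product SMILES of the product; must contain the scheme's cut
#'   pattern exactly once.
#' @param scheme a \code{\link{amide_scheme}} (the only built-in scheme).
#' @param acid_pool,amine_pool character vectors of building-block SMILES.
#' @return list with \code{fragments} (named acid/amine SMILES of the
#'   decomposition) and \code{analogs} (canonical SMILES of the enumerated
#'   products).
#' @export
decompose_and_enumerate <- function(product, scheme = amide_scheme(),
                                    acid_pool = character(0),
                                    amine_pool = character(0)) {
  if (!inherits(scheme, "reaction_scheme") || scheme$id != "amide")
    stop("only the amide scheme is implemented")
  frags <- amide_decompose(product)
  analogs <- character(0)
  if (length(acid_pool) && length(amine_pool)) {
    prods <- as.vector(vapply(acid_pool, function(a)
      vapply(amine_pool, function(m) amide_couple(a, m), character(1)),
      character(length(amine_pool))))
    analogs <- unique(canonical_smiles(prods))
  }
  list(fragments = frags, analogs = analogs)
}

# retro: cut the unique amide bond, cap the carbonyl with OH
amide_decompose <- function(product) {
  g <- mol_graph_from_smiles(product)
  hits <- find_amide_bonds(g)
  if (length(hits) == 0) stop("product contains no amide cut site")
  if (length(hits) > 1) stop("product contains multiple amide cut sites")
  h <- hits[[1]]
  acid_atoms <- component_of(g, h["C"], h["bond"])
  amine_atoms <- component_of(g, h["N"], h["bond"])
  # cap the carbonyl carbon with a hydroxyl oxygen
  g2 <- g
  g2$atoms <- rbind(g2$atoms, data.frame(element = "O", x = 0, y = 0, z = 0,
                                         formal_charge = 0))
  new_o <- nrow(g2$atoms)
  g2$bonds <- rbind(g2$bonds, data.frame(a1 = h[["C"]], a2 = new_o,
                                         order = 1L))
  acid <- subgraph_smiles(g2, c(acid_atoms, new_o), id = "acid")
  amine <- subgraph_smiles(g, amine_atoms, id = "amine")
  c(acid = acid, amine = amine)
}

# forward: condense acid + amine to the amide (lose the acid OH)
amide_couple <- function(acid, amine) {
  ga <- mol_graph_from_smiles(acid)
  gm <- mol_graph_from_smiles(amine)
  oh <- find_acidic_hydroxyls(ga)
  if (length(oh) == 0) stop("acid reagent has no carboxylic acid group: ", acid)
  oh <- oh[1]
  adj <- graph_adjacency(ga)
  cc <- adj[[oh]][1]  # the carbonyl carbon
  # the amine nitrogen: first basic-amine N, else first all-single-bond N
  nn <- find_basic_amines(gm)
  if (length(nn) == 0) {
    nn <- which(gm$atoms$element == "N" & gm$atoms$formal_charge == 0)
    nn <- nn[vapply(nn, function(v) {
      nb <- graph_adjacency(gm)[[v]]
      length(nb) <= 2L && all(vapply(nb, function(w)
        bond_order_between(gm, v, w) == 1L, logical(1)))
    }, logical(1))]
  }
  if (length(nn) == 0) stop("amine reagent has no couplable nitrogen: ", amine)
  nn <- nn[1]
  keep <- setdiff(seq_len(nrow(ga$atoms)), oh)
  remap <- match(seq_len(nrow(ga$atoms)), keep)
  atoms <- rbind(ga$atoms[keep, , drop = FALSE], gm$atoms)
  off <- length(keep)
  bsel <- ga$bonds$a1 != oh & ga$bonds$a2 != oh
  bonds <- rbind(
    data.frame(a1 = remap[ga$bonds$a1[bsel]], a2 = remap[ga$bonds$a2[bsel]],
               order = ga$bonds$order[bsel]),
    data.frame(a1 = gm$bonds$a1 + off, a2 = gm$bonds$a2 + off,
               order = gm$bonds$order),
    data.frame(a1 = remap[cc], a2 = nn + off, order = 1L))
  rownames(atoms) <- NULL
  graph_to_smiles(atoms, bonds, id = "amide")
}
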