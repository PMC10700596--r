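# Hit-picking cascade on ranked docking output: top-N selection, greedy
# fingerprint leader clustering, novelty filtering against known ligands,
# torsion-strain thresholding and required-interaction checks. Every stage
# logs in/out counts and rejected ids so the report telescopes.

# Tanimoto between two fingerprints stored as sorted set-bit index vectors
tc_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Greedy leader clustering by fingerprint Tanimoto
#'
#' Records must arrive sorted best-score-first. Walking down the ranking,
#' each record joins the first existing cluster whose head has Tc >=
#' \code{tc_cutoff} to it, otherwise it founds a new cluster — so every head
#' is its cluster's best-scoring member by construction.
#'
#' @param records data.frame with at least an \code{id} column, sorted
#'   best-first.
#' @param fingerprints list of set-bit index vectors aligned with
#'   \code{records} (e.g. the \code{fingerprint} column of
#'   \code{\link{compute_properties}}).
#' @param tc_cutoff Tanimoto threshold for joining a cluster (default 0.5,
#'   inclusive).
#' @return \code{records} with added columns \code{cluster} (head index,
#'   1-based in head discovery order) and \code{is_head}.
#' @export
cluster_by_fingerprint <- function(records, fingerprints, tc_cutoff = 0.5) {
  n <- nrow(records)
  if (length(fingerprints) != n)
    stop("fingerprints must align with records")
  cluster <- integer(n)
  heads <- integer(0)
  for (i in seq_len(n)) {
    assigned <- 0L
    for (hk in seq_along(heads)) {
      if (tc_bits(fingerprints[[i]], fingerprints[[heads[hk]]]) >= tc_cutoff) {
        assigned <- hk
        break
      }
    }
    if (assigned == 0L) {
      heads <- c(heads, i)
      assigned <- length(heads)
    }
    cluster[i] <- assigned
  }
  records$cluster <- cluster
  records$is_head <- seq_len(n) %in% heads
  records
}

#' Novelty filter against known ligands
#'
#' Removes every record whose maximum Tanimoto to any known ligand reaches
#' \code{tc_cutoff} (inclusive boundary: Tc equal to the cutoff is
#' removed). An empty known set retains everything, with a warning.
#'
#' @param records data.frame with an \code{id} column.
#' @param fingerprints list of set-bit index vectors aligned with
#'   \code{records}.
#' @param known_fingerprints list of set-bit index vectors of the known
#'   ligands (names used in the removal log).
#' @param tc_cutoff removal threshold (default 0.35).
#' @return list with \code{records} (retained subset), \code{removed}
#'   (data.frame id, max_tc, offender).
#' @export
novelty_filter <- function(records, fingerprints, known_fingerprints,
                           tc_cutoff = 0.35) {
  if (length(known_fingerprints) == 0) {
    warning("empty known-ligand set: retaining all records")
    return(list(records = records,
                removed = data.frame(id = character(0), max_tc = numeric(0),
                                     offender = character(0))))
  }
  kn <- names(known_fingerprints) %||%
    sprintf("known%03d", seq_along(known_fingerprints))
  max_tc <- numeric(nrow(records))
  offender <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    tcs <- vapply(known_fingerprints, function(k)
      tc_bits(fingerprints[[i]], k), numeric(1))
    j <- which.max(tcs)
    max_tc[i] <- tcs[j]
    offender[i] <- kn[j]
  }
  drop <- max_tc >= tc_cutoff
  list(records = records[!drop, , drop = FALSE],
       removed = data.frame(id = records$id[drop], max_tc = max_tc[drop],
                            offender = offender[drop],
                            stringsAsFactors = FALSE))
}

# ---- torsion strain -------------------------------------------------------

#' Default torsion-strain rule table
#'
#' A compact built-in rule set in torsion energy units (TEU): biaryl links,
#' amide cis/trans, esters and rotors alpha to a carbonyl. Each rule maps a
#' dihedral environment (identified by a graph matcher, not a general SMARTS
#' engine) to a piecewise-linear TEU profile over the absolute dihedral
#' angle 0-180 degrees. Override any profile from TSV with
#' \code{\link{read_torsion_rules}}.
#'
#' @return list of rules; each rule has \code{id} and \code{profile}
#'   (data.frame \code{angle}, \code{teu}).
#' @export
default_torsion_rules <- function() {
  prof <- function(a, t) data.frame(angle = a, teu = t)
  list(
    list(id = "biaryl",
         profile = prof(c(0, 40, 90, 140, 180), c(2.0, 0, 0.6, 0, 2.0))),
    list(id = "amide",
         profile = prof(c(0, 60, 120, 180), c(1.5, 2.5, 2.5, 0))),
    list(id = "ester",
         profile = prof(c(0, 90, 180), c(0, 2.5, 1.0))),
    list(id = "alpha_carbonyl",
         profile = prof(c(0, 60, 120, 180), c(0.8, 0.2, 0.8, 0.2))))
}

#' Read torsion-strain profiles from TSV
#'
#' Long-format TSV with header columns \code{rule_id}, \code{angle},
#' \code{teu}; rule ids must be among the built-in matchers (biaryl, amide,
#' ester, alpha_carbonyl). Rows replace the corresponding built-in profile.
#'
#' @param file TSV path.
#' @return rule list as \code{\link{default_torsion_rules}}.
#' @export
read_torsion_rules <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  rules <- default_torsion_rules()
  ids <- vapply(rules, `[[`, character(1), "id")
  for (rid in unique(tab$rule_id)) {
    k <- match(rid, ids)
    if (is.na(k)) stop("unknown torsion rule id: ", rid)
    sub <- tab[tab$rule_id == rid, ]
    rules[[k]]$profile <- data.frame(angle = sub$angle, teu = sub$teu)
  }
  rules
}

# signed dihedral angle (degrees) of four points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb
  atan2(y, x) * 180 / pi
}

# linear TEU lookup on the |angle| in [0, 180] profile
teu_lookup <- function(profile, angle) {
  a <- abs(((angle + 180) %% 360) - 180)  # fold to [0, 180]
  stats::approx(profile$angle, profile$teu, xout = a, rule = 2)$y
}

# per-rule bond matchers: given graph and a rotatable bond (i, j), return a
# dihedral quadruple or NULL
match_torsion_rule <- function(rule_id, g, i, j, adj, ring_atoms) {
  pick <- function(cands) if (length(cands)) min(cands) else NA_integer_
  quad <- switch(
    rule_id,
    biaryl = {
      if (ring_atoms[i] && ring_atoms[j]) {
        n1 <- pick(setdiff(adj[[i]][ring_atoms[adj[[i]]]], j))
        n2 <- pick(setdiff(adj[[j]][ring_atoms[adj[[j]]]], i))
        if (!is.na(n1) && !is.na(n2)) c(n1, i, j, n2) else NULL
      } else NULL
    },
    amide = {
      amide_quad(g, i, j, adj)
    },
    ester = {
      # C(=O)-O-C single bond at the ester oxygen
      for (sw in 1:2) {
        o <- if (sw == 1) i else j
        c2 <- if (sw == 1) j else i
        if (g$atoms$element[o] == "O" && g$atoms$element[c2] == "C") {
          cc <- setdiff(adj[[o]], c2)
          cc <- cc[vapply(cc, function(k) g$atoms$element[k] == "C" &&
                            any(vapply(adj[[k]], function(w)
                              g$atoms$element[w] == "O" &&
                                bond_order_between(g, k, w) == 2L,
                              logical(1))), logical(1))]
          if (length(cc)) {
            ox <- adj[[cc[1]]][vapply(adj[[cc[1]]], function(w)
              g$atoms$element[w] == "O" &&
                bond_order_between(g, cc[1], w) == 2L, logical(1))][1]
            n2 <- pick(setdiff(adj[[c2]], o))
            if (!is.na(n2)) return(c(ox, cc[1], o, c2))
          }
        }
      }
      NULL
    },
    alpha_carbonyl = {
      for (sw in 1:2) {
        ca <- if (sw == 1) i else j
        cb <- if (sw == 1) j else i
        if (g$atoms$element[cb] == "C") {
          ox <- adj[[cb]][vapply(adj[[cb]], function(w)
            g$atoms$element[w] == "O" && bond_order_between(g, cb, w) == 2L,
            logical(1))]
          if (length(ox)) {
            n1 <- pick(setdiff(adj[[ca]], cb))
            if (!is.na(n1)) return(c(n1, ca, cb, ox[1]))
          }
        }
      }
      NULL
    },
    NULL)
  quad
}

amide_quad <- function(g, i, j, adj) {
  for (sw in 1:2) {
    cc <- if (sw == 1) i else j
    nn <- if (sw == 1) j else i
    if (g$atoms$element[cc] == "C" && g$atoms$element[nn] == "N") {
      ox <- adj[[cc]][vapply(adj[[cc]], function(w)
        g$atoms$element[w] == "O" && bond_order_between(g, cc, w) == 2L,
        logical(1))]
      if (length(ox)) {
        n2 <- setdiff(adj[[nn]], cc)
        if (length(n2)) return(c(ox[1], cc, nn, min(n2)))
      }
    }
  }
  NULL
}

#' Torsion strain of a posed molecule
#'
#' Walks every rotatable dihedral of the 3D molecule, looks up the TEU at
#' the pose's dihedral angle from the first matching rule (rule order is
#' precedence) and reports the per-dihedral energies. Dihedrals matching no
#' rule contribute 0 TEU and are logged as uncovered.
#'
#' @param mol list with \code{atoms} (data.frame element, x, y, z and
#'   optionally formal_charge) and \code{bonds} (data.frame a1, a2, order).
#' @param rules torsion rules (default \code{\link{default_torsion_rules}}).
#' @return Object of class \code{strain_result}: list with
#'   \code{dihedrals} (data.frame bond atoms, rule_id, angle, teu),
#'   \code{max_teu} and \code{n_uncovered}.
#' @export
measure_strain <- function(mol, rules = default_torsion_rules()) {
  g <- list(atoms = mol$atoms, bonds = mol$bonds)
  if (is.null(g$atoms$formal_charge)) g$atoms$formal_charge <- 0
  rot <- which(strain_bond_flags(g))
  adj <- graph_adjacency(g)
  ring <- rep(FALSE, nrow(g$atoms))
  rb <- ring_bond_flags(g)
  if (any(rb)) ring[unique(c(g$bonds$a1[rb], g$bonds$a2[rb]))] <- TRUE
  xyz <- as.matrix(g$atoms[, c("x", "y", "z")])
  rows <- list()
  n_unc <- 0L
  for (b in rot) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    hit <- NULL
    for (r in rules) {
      quad <- match_torsion_rule(r$id, g, i, j, adj, ring)
      if (!is.null(quad)) {
        ang <- dihedral_angle(xyz[quad[1], ], xyz[quad[2], ],
                              xyz[quad[3], ], xyz[quad[4], ])
        hit <- data.frame(a1 = i, a2 = j, rule_id = r$id, angle = ang,
                          teu = teu_lookup(r$profile, ang),
                          stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(hit)) {
      n_unc <- n_unc + 1L
      hit <- data.frame(a1 = i, a2 = j, rule_id = NA_character_,
                        angle = NA_real_, teu = 0, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- hit
  }
  dihedrals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a1 = integer(0), a2 = integer(0), rule_id = character(0),
               angle = numeric(0), teu = numeric(0))
  structure(list(dihedrals = dihedrals,
                 max_teu = if (nrow(dihedrals)) max(dihedrals$teu) else 0,
                 n_uncovered = n_unc),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf("strain: %d rotatable dihedrals, max TEU %.2f (%d uncovered)\n",
              nrow(x$dihedrals), x$max_teu, x$n_uncovered))
  invisible(x)
}

#' Torsion-strain filter
#'
#' @param mols named list of posed molecules (see
#'   \code{\link{measure_strain}}).
#' @param rules torsion rule table.
#' @param teu_cutoff maximum allowed TEU of the single most strained
#'   dihedral (default 1.5, inclusive: max TEU equal to the cutoff passes).
#' @return list with \code{pass} (named logical), \code{strain} (named list
#'   of \code{strain_result}s).
#' @export
strain_filter <- function(mols, rules = default_torsion_rules(),
                          teu_cutoff = 1.5) {
  strain <- lapply(mols, measure_strain, rules = rules)
  pass <- vapply(strain, function(s) s$max_teu <= teu_cutoff, logical(1))
  names(pass) <- names(mols)
  list(pass = pass, strain = strain)
}

# ---- required interactions ------------------------------------------------

parse_residue_label <- function(label, receptor) {
  resno <- suppressWarnings(as.integer(gsub("[^0-9]", "", label)))
  if (is.na(resno)) stop("cannot parse residue label: ", label)
  if (!any(receptor$resno == resno))
    stop("required residue ", label, " absent from receptor")
  resno
}

#' Required-interaction check of a docked pose
#'
#' Codifies pose inspection: a hydrogen bond requires a donor-acceptor
#' heavy-atom distance <= 3.5 Angstrom (inclusive) and a donor angle >= 120
#' degrees (measured at the donor through its bonded hydrogen when explicit
#' hydrogens are present, else through its bonded heavy-atom antecedent; a
#' donor with no recorded neighbour passes on distance alone). An ionic
#' contact requires a ligand formal charge and a receptor partial charge of
#' opposite sign (|q| >= 0.2 e) within 4.0 Angstrom. The pose passes iff
#' every required contact is found.
#'
#' @param pose_atoms data.frame of ligand atoms: \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{formal_charge}.
#' @param bonds optional two-column matrix of ligand bond index pairs (used
#'   for donor angles).
#' @param receptor a \code{\link{receptor_model}} in the same frame.
#' @param required data.frame with columns \code{residue} (label such as
#'   "R316" or a residue number) and \code{type} ("hbond" or "ionic").
#' @param hbond_dist,hbond_angle,ionic_dist geometric thresholds.
#' @return list with \code{pass} and \code{contacts} (data.frame residue,
#'   type, distance, angle).
#' @export
interaction_filter <- function(pose_atoms, receptor, required, bonds = NULL,
                               hbond_dist = 3.5, hbond_angle = 120,
                               ionic_dist = 4.0) {
  lig_xyz <- as.matrix(pose_atoms[, c("x", "y", "z")])
  rec_xyz <- receptor_coords(receptor)
  contacts <- list()
  ok <- logical(nrow(required))
  for (k in seq_len(nrow(required))) {
    resno <- parse_residue_label(required$residue[k], receptor)
    res_idx <- which(receptor$resno == resno)
    type <- required$type[k]
    found <- FALSE
    best <- c(distance = NA_real_, angle = NA_real_)
    if (type == "hbond") {
      lig_polar <- which(pose_atoms$element %in% c("N", "O"))
      rec_polar <- res_idx[receptor$element[res_idx] %in% c("N", "O")]
      for (li in lig_polar) for (ri in rec_polar) {
        d <- sqrt(sum((lig_xyz[li, ] - rec_xyz[ri, ])^2))
        if (d > hbond_dist) next
        ang <- donor_angle(li, ri, pose_atoms, lig_xyz, rec_xyz, bonds)
        if (is.na(ang) || ang >= hbond_angle) {
          found <- TRUE
          best <- c(distance = d, angle = ang)
          break
        }
      }
    } else if (type == "ionic") {
      lig_chg <- which(pose_atoms$formal_charge != 0)
      rec_chg <- res_idx[abs(receptor$charge[res_idx]) >= 0.2]
      for (li in lig_chg) for (ri in rec_chg) {
        if (sign(pose_atoms$formal_charge[li]) ==
            sign(receptor$charge[ri])) next
        d <- sqrt(sum((lig_xyz[li, ] - rec_xyz[ri, ])^2))
        if (d <= ionic_dist) {
          found <- TRUE
          best <- c(distance = d, angle = NA_real_)
          break
        }
      }
    } else stop("unknown contact type: ", type)
    ok[k] <- found
    contacts[[k]] <- data.frame(residue = required$residue[k], type = type,
                                distance = best["distance"],
                                angle = best["angle"], found = found,
                                stringsAsFactors = FALSE)
  }
  contacts <- do.call(rbind, contacts)
  rownames(contacts) <- NULL
  list(pass = all(ok), contacts = contacts)
}

# donor angle: D-H...A measured at the hydrogen when an explicit H is
# bonded to the donor, else the X-D...A angle at the donor through its first
# bonded heavy neighbour; NA when no neighbour is known
donor_angle <- function(li, ri, pose_atoms, lig_xyz, rec_xyz, bonds) {
  if (is.null(bonds)) return(NA_real_)
  nb <- c(bonds[bonds[, 1] == li, 2], bonds[bonds[, 2] == li, 1])
  if (length(nb) == 0) return(NA_real_)
  hs <- nb[pose_atoms$element[nb] == "H"]
  angle_at <- function(vertex, p1, p2) {
    v1 <- p1 - vertex; v2 <- p2 - vertex
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  if (length(hs))
    angle_at(lig_xyz[hs[1], ], lig_xyz[li, ], rec_xyz[ri, ])
  else
    angle_at(lig_xyz[li, ], lig_xyz[nb[1], ], rec_xyz[ri, ])
}

# ---- cascade --------------------------------------------------------------

#' Run the full hit-triage cascade
#'
#' top-N selection, fingerprint leader clustering (heads only survive),
#' novelty filtering, and optional strain and interaction stages, with a
#' telescoping stage log.
#'
#' @param ranked data.frame (id, score columns) sorted best-first, e.g. from
#'   \code{\link{rank_library}} (its \code{e_total} is used as score when no
#'   \code{score} column exists).
#' @param fingerprints named list of set-bit index vectors covering every
#'   ranked id.
#' @param known_fingerprints known-ligand fingerprints for the novelty
#'   stage (may be empty: stage retains everything).
#' @param top_n ranking depth entering the cascade.
#' @param cluster_tc,novelty_tc,teu_cutoff stage thresholds.
#' @param mols optional named list of posed molecules for the strain stage
#'   (skipped when NULL).
#' @param torsion_rules strain rule table.
#' @return Object of class \code{triage_report}.
#' @export
run_triage <- function(ranked, fingerprints, known_fingerprints = list(),
                       top_n = nrow(ranked), cluster_tc = 0.5,
                       novelty_tc = 0.35, teu_cutoff = 1.5, mols = NULL,
                       torsion_rules = default_torsion_rules()) {
  if (is.null(ranked$score)) ranked$score <- ranked$e_total
  stages <- list()
  log_stage <- function(name, params, n_in, n_out, rejected) {
    stages[[length(stages) + 1L]] <<- list(stage = name, params = params,
                                           n_in = n_in, n_out = n_out,
                                           rejected = rejected)
  }
  cur <- ranked
  sel <- utils::head(cur, top_n)
  log_stage("top_n", list(top_n = top_n), nrow(cur), nrow(sel),
            setdiff(cur$id, sel$id))
  cur <- sel

  fps <- fingerprints[cur$id]
  cl <- cluster_by_fingerprint(cur, fps, tc_cutoff = cluster_tc)
  heads <- cl[cl$is_head, , drop = FALSE]
  log_stage("cluster", list(tc_cutoff = cluster_tc), nrow(cur), nrow(heads),
            setdiff(cur$id, heads$id))
  cur <- heads

  nv <- suppressWarnings(
    novelty_filter(cur, fingerprints[cur$id], known_fingerprints,
                   tc_cutoff = novelty_tc))
  log_stage("novelty", list(tc_cutoff = novelty_tc), nrow(cur),
            nrow(nv$records), nv$removed$id)
  cur <- nv$records

  strain <- NULL
  if (!is.null(mols)) {
    sf <- strain_filter(mols[cur$id], rules = torsion_rules,
                        teu_cutoff = teu_cutoff)
    keep <- cur$id[sf$pass[cur$id]]
    log_stage("strain", list(teu_cutoff = teu_cutoff), nrow(cur),
              length(keep), setdiff(cur$id, keep))
    strain <- sf$strain
    cur <- cur[cur$id %in% keep, , drop = FALSE]
  }
  structure(list(input_size = nrow(ranked), stages = stages,
                 survivors = cur, strain = strain),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("triage report: %d in, %d surviving\n", x$input_size,
              nrow(x$survivors)))
  for (s in x$stages)
    cat(sprintf("  %-8s %5d -> %5d  (%s)\n", s$stage, s$n_in, s$n_out,
                paste(names(s$params), unlist(s$params), sep = "=",
                      collapse = ", ")))
  invisible(x)
}

#' Serialize a triage report to JSON
#' @param report a \code{triage_report}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_triage_report <- function(report, file) {
  out <- list(input_size = report$input_size,
              stages = lapply(report$stages, function(s)
                list(stage = s$stage, params = s$params, n_in = s$n_in,
                     n_out = s$n_out, rejected = s$rejected)),
              survivors = report$survivors$id)
  jsonlite::write_json(out, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
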