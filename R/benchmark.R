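# Control calculations for a docking setup: property-matched decoys, a
# charge-stratified "extrema" challenge set, and enrichment metrics (ROC
# AUC and the semilog early-enrichment adjusted logAUC).

#' Default decoy property-matching windows
#'
#' Half-widths of the per-ligand matching windows: molecular weight +/- 25
#' amu, clogP +/- 1.0, equal net charge, +/- 2 rotatable bonds, donors and
#' acceptors, with a Tanimoto dissimilarity cap of 0.35 to the own ligand.
#'
#' @return named list of window half-widths and the \code{tc_cap}.
#' @export
default_decoy_windows <- function() {
  list(mwt = 25, clogp = 1.0, charge = 0, rotatable_bonds = 2,
       hbd = 2, hba = 2, tc_cap = 0.35)
}

#' Property-matched decoy selection
#'
#' For each ligand, pool members inside every property window, below the
#' Tanimoto cap and not identical to the ligand (canonical SMILES) are
#' candidates; the \code{n_per_ligand} most dissimilar (lowest Tc, ties by
#' pool order) are selected. Shortfalls are reported, not padded.
#'
#' @param ligands,pool \code{\link{compute_properties}} data.frames.
#' @param n_per_ligand decoys requested per ligand.
#' @param windows matching windows (default
#'   \code{\link{default_decoy_windows}}).
#' @return Object of class \code{decoy_set}: list with \code{decoys} (named
#'   list of pool ids per ligand), \code{shortfall} (named integer),
#'   \code{windows}.
#' @export
make_property_matched_decoys <- function(ligands, pool, n_per_ligand = 50,
                                         windows = default_decoy_windows()) {
  if (nrow(pool) == 0) stop("decoy pool is empty")
  sel <- vector("list", nrow(ligands))
  names(sel) <- ligands$id
  shortfall <- stats::setNames(integer(nrow(ligands)), ligands$id)
  for (i in seq_len(nrow(ligands))) {
    ok <- abs(pool$mwt - ligands$mwt[i]) <= windows$mwt &
      abs(pool$clogp - ligands$clogp[i]) <= windows$clogp &
      abs(pool$net_charge - ligands$net_charge[i]) <= windows$charge &
      abs(pool$rotatable_bonds - ligands$rotatable_bonds[i]) <=
        windows$rotatable_bonds &
      abs(pool$hbd - ligands$hbd[i]) <= windows$hbd &
      abs(pool$hba - ligands$hba[i]) <= windows$hba &
      pool$cansmi != ligands$cansmi[i]
    tc <- vapply(seq_len(nrow(pool)), function(j)
      tc_bits(ligands$fingerprint[[i]], pool$fingerprint[[j]]), numeric(1))
    ok <- ok & tc < windows$tc_cap
    cand <- which(ok)
    cand <- cand[order(tc[cand], cand)]  # most dissimilar first, pool order ties
    take <- utils::head(cand, n_per_ligand)
    sel[[i]] <- pool$id[take]
    shortfall[i] <- max(0L, n_per_ligand - length(take))
  }
  structure(list(decoys = sel, shortfall = shortfall, windows = windows),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("decoy set: %d ligands, %d decoys total (%d short)\n",
              length(x$decoys), sum(lengths(x$decoys)), sum(x$shortfall)))
  invisible(x)
}

#' Charge-stratified extrema challenge set
#'
#' Draws a seeded stratified sample per net-charge class from a
#' property-annotated pool, keeping the class labels. Classes are
#' \code{"+1"} (net charge >= +1), \code{"0"}, \code{"-1"} and
#' \code{"<=-2"}.
#'
#' @param pool \code{\link{compute_properties}} data.frame.
#' @param composition named integer vector of requested counts per class
#'   (names among "+1", "0", "-1", "<=-2").
#' @param seed integer seed.
#' @return data.frame: the sampled records with a \code{charge_class}
#'   column.
#' @export
make_extrema_set <- function(pool, composition, seed = 1L) {
  cls <- charge_class(pool$net_charge)
  out <- list()
  with_seed(seed, {
    for (cl in names(composition)) {
      idx <- which(cls == cl)
      k <- composition[[cl]]
      if (length(idx) < k)
        stop(sprintf("charge class %s: only %d of %d requested available",
                     cl, length(idx), k))
      take <- sort(sample(idx, k))
      sub <- pool[take, , drop = FALSE]
      sub$charge_class <- cl
      out[[cl]] <- sub
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

charge_class <- function(q) {
  ifelse(q >= 1, "+1", ifelse(q == 0, "0", ifelse(q == -1, "-1", "<=-2")))
}

#' Enrichment metrics: ROC AUC and adjusted logAUC
#'
#' Ranks by docking favorability (ascending score: lower = better), builds
#' the ROC with tied scores collapsed to single diagonal steps (equivalent
#' to the tie-averaged Mann-Whitney statistic), and computes the trapezoid
#' AUC plus the early-enrichment adjusted logAUC: the integral of TPR over
#' log10 FPR from \code{log_floor} to 1, normalised by |log10 log_floor|,
#' minus the same integral of the random diagonal (random = 0, perfect
#' separation ~ 0.8554 at the default floor).
#'
#' @param scores data.frame with columns \code{score} and \code{is_ligand}.
#' @param log_floor lower FPR limit of the semilog integral (default 1e-3).
#' @return Object of class \code{enrichment_result}: list with
#'   \code{roc} (data.frame fpr, tpr), \code{auc}, \code{adjusted_logauc},
#'   \code{n_ligands}, \code{n_decoys}.
#' @export
enrichment_metrics <- function(scores, log_floor = 1e-3) {
  if (!all(c("score", "is_ligand") %in% names(scores)))
    stop("scores needs columns score, is_ligand")
  nl <- sum(scores$is_ligand); nd <- sum(!scores$is_ligand)
  if (nl == 0 || nd == 0)
    stop("need at least one ligand and one decoy")
  ord <- order(scores$score)
  s <- scores$score[ord]; lab <- scores$is_ligand[ord]
  # collapse tied scores into single ROC steps
  grp <- cumsum(!duplicated(s))
  counts <- rowsum(cbind(tp = as.numeric(lab), fp = as.numeric(!lab)), grp)
  counts <- counts[order(as.numeric(rownames(counts))), , drop = FALSE]
  tpr <- unname(c(0, cumsum(counts[, "tp"]) / nl))
  fpr <- unname(c(0, cumsum(counts[, "fp"]) / nd))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  adjusted <- logauc_from_roc(fpr, tpr, log_floor)
  structure(list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 adjusted_logauc = adjusted, n_ligands = nl, n_decoys = nd,
                 log_floor = log_floor),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d ligands vs %d decoys, AUC %.4f, adjusted logAUC %.4f\n",
              x$n_ligands, x$n_decoys, x$auc, x$adjusted_logauc))
  invisible(x)
}

# exact piecewise-linear semilog integral of the ROC minus the diagonal
logauc_from_roc <- function(fpr, tpr, log_floor) {
  # TPR as a function of FPR, linear between ROC vertices; clamp at floor
  seg_int <- function(f0, f1, t0, t1) {
    # integral of t(f) d(log10 f) on [f0, f1], t linear in f
    if (f1 <= f0) return(0)
    b <- (t1 - t0) / (f1 - f0)
    a <- t0 - b * f0
    (a * log(f1 / f0) + b * (f1 - f0)) / log(10)
  }
  total <- 0
  for (k in seq_len(length(fpr) - 1)) {
    f0 <- fpr[k]; f1 <- fpr[k + 1]
    t0 <- tpr[k]; t1 <- tpr[k + 1]
    if (f1 <= log_floor) next
    if (f0 < log_floor) {
      # interpolate the vertex at the floor
      t_at <- if (f1 > f0) t0 + (t1 - t0) * (log_floor - f0) / (f1 - f0) else t1
      f0 <- log_floor; t0 <- t_at
    }
    if (f0 <= 0) { f0 <- log_floor }  # vertical jump at fpr = 0
    total <- total + seg_int(f0, f1, t0, t1)
  }
  random <- (1 - log_floor) / log(10)
  (total - random) / abs(log10(log_floor))
}

#' Charge-composition enrichment check
#'
#' Compares the net-charge class composition of the top-ranked fraction of
#' an extrema screen with the overall composition; the check passes when
#' monoanions are at least as prevalent among top ranks as overall.
#'
#' @param results data.frame with columns \code{score} (lower = better) and
#'   \code{charge_class}.
#' @param top_fraction fraction of the ranking considered "top"
#'   (default 0.1).
#' @return list with \code{top_composition}, \code{overall_composition}
#'   (named proportions), \code{monoanion_top}, \code{monoanion_overall}
#'   and \code{pass}.
#' @export
charge_enrichment_check <- function(results, top_fraction = 0.1) {
  if (!all(c("score", "charge_class") %in% names(results)))
    stop("results needs columns score, charge_class")
  n_top <- max(1L, floor(nrow(results) * top_fraction))
  ord <- order(results$score)
  top <- results$charge_class[ord][seq_len(n_top)]
  lev <- unique(results$charge_class)
  comp <- function(x) prop.table(table(factor(x, levels = lev)))
  top_comp <- comp(top)
  all_comp <- comp(results$charge_class)
  mono_top <- if ("-1" %in% lev) as.numeric(top_comp[["-1"]]) else 0
  mono_all <- if ("-1" %in% lev) as.numeric(all_comp[["-1"]]) else 0
  list(top_composition = top_comp, overall_composition = all_comp,
       monoanion_top = mono_top, monoanion_overall = mono_all,
       pass = mono_top >= mono_all)
}
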