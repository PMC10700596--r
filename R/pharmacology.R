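# Assay and PK arithmetic: 4PL dose-response fits, Cheng-Prusoff
# conversion, Schild regression, ligand efficiency, noncompartmental PK
# with below-LLOQ censoring rules, and oral bioavailability.

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal/(mol K)

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \code{y = bottom + (top - bottom) / (1 + 10^((log10 x - log10 XC50) h))}
#' (inhibition convention: response falls with concentration for h > 0; the
#' stimulation model flips the sign of the exponent). Fitting is by
#' Levenberg-Marquardt with multi-start initialisation over five log-spaced
#' XC50 seeds spanning the tested concentrations.
#'
#' @param data a \code{\link{make_dose_response}} object or data.frame with
#'   columns \code{concentration} (molar, > 0) and \code{response}.
#' @param model \code{"inhibition"} (XC50 is an IC50) or
#'   \code{"stimulation"} (an EC50).
#' @return Object of class \code{drfit}: coefficients \code{ic50} (or
#'   \code{ec50}), \code{hill}, \code{top}, \code{bottom}, plus residual SD
#'   and a convergence flag.
#' @export
fit_dose_response <- function(data, model = c("inhibition", "stimulation")) {
  model <- match.arg(model)
  conc <- data$concentration
  resp <- data$response
  if (length(unique(conc)) < 4L)
    stop("at least 4 distinct concentrations are required")
  if (any(conc <= 0)) stop("concentrations must be positive")
  rng <- diff(range(resp))
  if (rng < max(1e-8, 1e-3 * stats::sd(resp) + 1e-8) || rng == 0)
    stop("flat response: no dose-response signal to fit")
  sgn <- if (model == "inhibition") 1 else -1
  fml <- resp ~ bottom + (top - bottom) /
    (1 + 10^(sgn * (log10(conc) - lx) * hill))
  starts <- seq(min(log10(conc)), max(log10(conc)), length.out = 5)
  best <- NULL
  for (lx0 in starts) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      fml, start = list(bottom = min(resp), top = max(resp), lx = lx0,
                        hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("4PL fit failed from every start")
  cf <- stats::coef(best$fit)
  converged <- best$fit$convInfo$isConv %||% TRUE
  est <- list(xc50 = 10^cf[["lx"]], hill = cf[["hill"]], top = cf[["top"]],
              bottom = cf[["bottom"]])
  if (est$top < est$bottom) {  # canonical orientation
    tmp <- est$top; est$top <- est$bottom; est$bottom <- tmp
    est$hill <- -est$hill
  }
  structure(list(model = model, ic50 = if (model == "inhibition") est$xc50
                 else NA_real_,
                 ec50 = if (model == "stimulation") est$xc50 else NA_real_,
                 xc50 = est$xc50, hill = est$hill, top = est$top,
                 bottom = est$bottom,
                 residual_sd = sqrt(best$rss /
                                      max(1, length(resp) - 4)),
                 converged = isTRUE(converged), data = data.frame(
                   concentration = conc, response = resp), nls = best$fit),
            class = "drfit")
}

#' @export
print.drfit <- function(x, ...) {
  lab <- if (x$model == "inhibition") "IC50" else "EC50"
  cat(sprintf("4PL %s fit: %s = %.3g M, hill = %.2f, top = %.1f, bottom = %.1f%s\n",
              x$model, lab, x$xc50, x$hill, x$top, x$bottom,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.drfit <- function(object, ...) {
  c(xc50 = object$xc50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
summary.drfit <- function(object, ...) {
  cat(sprintf("4PL %s fit on %d points\n", object$model,
              nrow(object$data)))
  print(object)
  cat(sprintf("residual SD %.3f, converged: %s\n", object$residual_sd,
              object$converged))
  invisible(object)
}

#' @export
predict.drfit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
  else newdata$concentration %||% newdata
  sgn <- if (object$model == "inhibition") 1 else -1
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(sgn * (log10(conc) - log10(object$xc50)) * object$hill))
}

#' @export
residuals.drfit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.drfit <- function(x, ...) {
  graphics::plot(x$data$concentration, x$data$response, log = "x",
                 xlab = "concentration (M)", ylab = "response (%)", ...)
  cc <- 10^seq(log10(min(x$data$concentration)),
               log10(max(x$data$concentration)), length.out = 100)
  graphics::lines(cc, predict(x, cc))
  graphics::abline(v = x$xc50, lty = 2)
  invisible(x)
}

#' Cheng-Prusoff conversion of a functional IC50 to Ki
#'
#' \code{Ki = IC50 / (S / Km + 1)} with S the agonist assay concentration
#' (e.g. its EC80) and Km the agonist's EC50.
#'
#' @param ic50,S,Km molar quantities, all > 0.
#' @return Ki in molar.
#' @export
cheng_prusoff <- function(ic50, S, Km) {
  if (any(c(ic50, S, Km) <= 0)) stop("all inputs must be positive")
  ic50 / (S / Km + 1)
}

#' Ligand efficiency
#'
#' \code{LE = -R T ln(Ki) / N} in kcal/mol per heavy atom, with
#' R = 1.987e-3 kcal/(mol K).
#'
#' @param ki inhibition constant, molar (> 0).
#' @param heavy_atoms number of non-hydrogen atoms (>= 1).
#' @param temperature Kelvin (default 298).
#' @return ligand efficiency, kcal/mol per heavy atom.
#' @export
ligand_efficiency <- function(ki, heavy_atoms, temperature = 298) {
  if (any(ki <= 0)) stop("ki must be positive")
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be at least 1")
  -GAS_CONSTANT_KCAL * temperature * log(ki) / heavy_atoms
}

#' Noncompartmental PK analysis
#'
#' Censored (below-LLOQ) concentrations are set to zero for the AUC, which
#' is the linear trapezoid over the observed span with no terminal
#' extrapolation (AUC_0-t). Cmax/Tmax come from the quantifiable points.
#' The terminal half-life is ln(2)/k from a log-linear regression over the
#' longest terminal run of at least three strictly quantifiable, strictly
#' declining points (censored points never enter the regression); with no
#' such run the half-life is absent.
#'
#' @param profile a \code{\link{make_pk_profile}} object or data.frame with
#'   columns \code{time}, \code{conc}, \code{censored}.
#' @return Object of class \code{pk_summary}: list with \code{auc}
#'   (ng*min/ml), \code{cmax}, \code{tmax}, \code{t_half} (min or NA),
#'   \code{points_used_for_t_half}.
#' @export
nca <- function(profile) {
  t <- profile$time
  cen <- profile$censored
  conc <- ifelse(cen, 0, profile$conc)
  if (all(cen)) stop("profile is entirely below the LLOQ")
  if (sum(!cen) < 2L) stop("need at least 2 quantifiable timepoints")
  auc <- sum(diff(t) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  qt <- which(!cen)
  cmax <- max(conc[qt])
  tmax <- t[qt[which.max(conc[qt])]]
  # longest terminal run of strictly declining points among the
  # quantifiable ones (censored points are discarded, not run-breaking)
  run <- integer(0)
  for (i in rev(qt)) {
    if (length(run) && conc[i] <= conc[run[1]]) break
    run <- c(i, run)
  }
  t_half <- NA_real_
  n_used <- length(run)
  if (length(run) >= 3L) {
    fit <- stats::lm(log(conc[run]) ~ t[run])
    k <- -stats::coef(fit)[[2]]
    if (k > 0) t_half <- log(2) / k else n_used <- 0L
  } else n_used <- 0L
  structure(list(auc = auc, cmax = cmax, tmax = tmax, t_half = t_half,
                 points_used_for_t_half = n_used),
            class = "pk_summary")
}

#' @export
print.pk_summary <- function(x, ...) {
  cat(sprintf("NCA: AUC %.3g ng*min/ml, Cmax %.3g ng/ml at %g min, T1/2 %s\n",
              x$auc, x$cmax, x$tmax,
              if (is.na(x$t_half)) "absent"
              else sprintf("%.1f min (%d pts)", x$t_half,
                           x$points_used_for_t_half)))
  invisible(x)
}

#' Oral bioavailability from dose-normalised AUC ratio
#'
#' \code{F = 100 (AUC_test / dose_test) / (AUC_ref / dose_ref)} with the
#' reference an intravenous administration.
#'
#' @param auc_ref,auc_test AUCs, ng*min/ml (> 0).
#' @param dose_ref,dose_test doses, mg/kg (> 0).
#' @return F in percent.
#' @export
oral_bioavailability <- function(auc_ref, dose_ref, auc_test, dose_test) {
  if (any(c(auc_ref, dose_ref, auc_test, dose_test) <= 0))
    stop("AUCs and doses must be positive")
  100 * (auc_test / dose_test) / (auc_ref / dose_ref)
}

#' Schild regression
#'
#' Linear regression of \code{log10(DR - 1)} on \code{log10 [B]} over
#' antagonist concentrations B with dose ratio DR > 1. The x-intercept is
#' -pA2 and \code{K_B = 10^(-pA2)}; K_B is only reported when the slope is
#' consistent with simple competitive antagonism (slope in [0.8, 1.2]),
#' otherwise the \code{competitive} flag is FALSE. Points with DR <= 1 are
#' excluded with a warning.
#'
#' @param dose_ratios data.frame with columns \code{conc} (antagonist,
#'   molar) and \code{dr} (dose ratio).
#' @return Object of class \code{schild_fit}: list with \code{slope},
#'   \code{pA2}, \code{K_B} (NA when not competitive), \code{competitive},
#'   \code{n_used}.
#' @export
schild_analysis <- function(dose_ratios) {
  usable <- dose_ratios$dr > 1
  if (any(!usable))
    warning(sum(!usable), " point(s) with DR <= 1 excluded")
  d <- dose_ratios[usable, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 usable (DR > 1) points")
  x <- log10(d$conc)
  y <- log10(d$dr - 1)
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[[2]]
  intercept <- stats::coef(fit)[[1]]
  pA2 <- -(-intercept / slope)  # x-intercept is -pA2
  competitive <- slope >= 0.8 && slope <= 1.2
  structure(list(slope = slope, pA2 = pA2,
                 K_B = if (competitive) 10^(-pA2) else NA_real_,
                 competitive = competitive, n_used = nrow(d), lm = fit),
            class = "schild_fit")
}

#' @export
print.schild_fit <- function(x, ...) {
  cat(sprintf("Schild regression: slope %.3f, pA2 %.3f%s (n = %d)\n",
              x$slope, x$pA2,
              if (x$competitive) sprintf(", K_B %.3g M", x$K_B)
              else "  [slope outside 0.8-1.2: not simple competitive]",
              x$n_used))
  invisible(x)
}

#' @export
coef.schild_fit <- function(object, ...) {
  c(slope = object$slope, pA2 = object$pA2, K_B = object$K_B)
}
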