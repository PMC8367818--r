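# Michaelis-Menten fitting for taxadiene synthase assays and derived
# parameter ratios.

#' Fit the Michaelis-Menten model to an enzyme assay
#'
#' Least-squares fit of v = Vmax S / (Km + S) by Levenberg-Marquardt,
#' initialised with Vmax0 = max(v) and Km0 = the substrate concentration
#' at half-maximal velocity (linear interpolation), run to a relative
#' parameter/objective tolerance of 1e-10 with at most 500 iterations.
#'
#' @param substrate substrate concentrations (uM, > 0; >= 4 points).
#' @param velocity matched reaction velocities.
#' @param enzymeConc molar enzyme concentration; when supplied,
#'   kcat = Vmax / enzymeConc is reported.
#' @return an [MMFit-class].
#' @examples
#' s <- c(0.2, 0.5, 1, 2.5, 5, 10, 25, 50)
#' fitMichaelisMenten(s, 1 * s / (8.6 + s))
#' @export
fitMichaelisMenten <- function(substrate, velocity, enzymeConc = NA_real_) {
  stopifnot(length(substrate) == length(velocity))
  if (length(substrate) < 4L)
    stop("need >= 4 assay points", call. = FALSE)
  if (any(substrate <= 0))
    stop("substrate concentrations must be > 0", call. = FALSE)
  ord <- order(substrate)
  if (all(diff(velocity[ord]) <= 0) && any(diff(velocity[ord]) < 0))
    warning("velocity decreases monotonically with substrate; ",
            "Michaelis-Menten model is inappropriate")
  vmax0 <- max(velocity)
  km0 <- tryCatch(
    stats::approx(velocity[ord], substrate[ord], xout = vmax0 / 2,
                  ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(substrate)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ Vmax * s / (Km + s),
      data = data.frame(s = substrate, v = velocity),
      start = list(Vmax = vmax0, Km = km0),
      lower = c(Vmax = 1e-12, Km = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500L, ftol = 1e-10,
                                           ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("MMFit", km = NA_real_, vmax = NA_real_, kcat = NA_real_,
               rss = NA_real_, converged = FALSE,
               fitted = rep(NA_real_, length(substrate))))
  }
  cf <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  new("MMFit", km = unname(cf["Km"]), vmax = unname(cf["Vmax"]),
      kcat = if (is.finite(enzymeConc) && enzymeConc > 0)
               unname(cf["Vmax"]) / enzymeConc else NA_real_,
      rss = sum(stats::residuals(fit)^2), converged = conv,
      fitted = as.numeric(stats::fitted(fit)))
}

#' Evaluate the Michaelis-Menten rate law
#'
#' @param substrate substrate concentrations.
#' @param km Michaelis constant.
#' @param vmax limiting rate.
#' @return velocities Vmax S / (Km + S).
#' @export
michaelisMenten <- function(substrate, km, vmax) {
  stopifnot(km > 0, vmax > 0)
  vmax * substrate / (km + substrate)
}

#' Parameter ratios between two Michaelis-Menten fits
#'
#' Ratios are second over first fit, the usual way of comparing an
#' isoform against a reference enzyme.
#'
#' @param fitA,fitB converged [MMFit-class] objects.
#' @return list with \code{kmRatio} and \code{kcatRatio} (kcat falls back
#'   to the Vmax ratio when neither fit carries an enzyme concentration).
#' @export
kineticRatios <- function(fitA, fitB) {
  stopifnot(is(fitA, "MMFit"), is(fitB, "MMFit"))
  if (!fitA@converged || !fitB@converged)
    stop("both fits must have converged", call. = FALSE)
  if (fitA@km <= 0 || fitA@vmax <= 0)
    stop("zero denominator in ratio", call. = FALSE)
  kcatRatio <- if (is.finite(fitA@kcat) && is.finite(fitB@kcat) &&
                   fitA@kcat > 0) fitB@kcat / fitA@kcat
               else fitB@vmax / fitA@vmax
  list(kmRatio = fitB@km / fitA@km, kcatRatio = kcatRatio)
}
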