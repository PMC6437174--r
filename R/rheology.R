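#' Empirical microvascular rheology parameters
#'
#' Coefficient sets for the three empirical laws that make blood flow in
#' microvessels non-Newtonian at the network scale:
#'
#' * the in-vivo apparent viscosity law (Fahraeus-Lindqvist effect plus the
#'   endothelial surface layer), used by [apparent_viscosity()];
#' * the Fahraeus law relating tube to discharge hematocrit, used by
#'   [fahraeus_tube_hematocrit()];
#' * the phase-separation (plasma skimming) law partitioning red-cell flux at
#'   diverging bifurcations, used by [phase_separation()].
#'
#' Defaults are the standard literature coefficient values; they are stored
#' here rather than hard-coded so alternative calibrations can be swapped in.
#'
#' @param plasma_viscosity Plasma viscosity in cP (default 1.2 at 37 C).
#' @param viscosity Named coefficients of the in-vivo viscosity law.
#' @param fahraeus Named coefficients of the Fahraeus law.
#' @param phase_separation Named coefficients `a`, `b`, `x0` of the
#'   phase-separation law.
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(plasma_viscosity = 1.2,
                            viscosity = c(mu45_a = 6, mu45_b = -0.085,
                                          mu45_c = 3.2, mu45_d = -2.44,
                                          mu45_e = -0.06, mu45_f = 0.645,
                                          esl = 1.1, href = 0.45),
                            fahraeus = c(a = 1.7, b = -0.415,
                                         c = -0.6, d = -0.011),
                            phase_separation = c(a = -6.96, b = 6.98,
                                                 x0 = 0.4)) {
  stopifnot(plasma_viscosity > 0)
  need <- function(x, nms, what) {
    if (!all(nms %in% names(x))) {
      abort(paste0("incomplete ", what, " coefficients; need ",
                   paste(nms, collapse = ", ")))
    }
    x
  }
  structure(
    list(
      plasma_viscosity = plasma_viscosity,
      viscosity = need(viscosity, c("mu45_a", "mu45_b", "mu45_c", "mu45_d",
                                    "mu45_e", "mu45_f", "esl", "href"),
                       "viscosity"),
      fahraeus = need(fahraeus, c("a", "b", "c", "d"), "Fahraeus"),
      phase_separation = need(phase_separation, c("a", "b", "x0"),
                              "phase separation")
    ),
    class = "rheology_params"
  )
}

#' In-vivo apparent blood viscosity
#'
#' Evaluates the empirical in-vivo viscosity law: relative viscosity is a
#' function of vessel diameter (Fahraeus-Lindqvist effect, with the sharp
#' rise below ~10 um produced by the endothelial surface layer term
#' `(D/(D-1.1))^2`) and of discharge hematocrit (strictly increasing). At
#' `hematocrit = 0` the law reduces to
#' `plasma_viscosity * (D/(D-1.1))^2`.
#'
#' @param diameter Vessel diameter(s), um; must exceed the endothelial layer
#'   scale (1.1 um).
#' @param hematocrit Discharge hematocrit(s) in `[0, 1)`.
#' @param params A [rheology_params()].
#' @return Apparent viscosity in cP, vectorized over inputs.
#' @examples
#' apparent_viscosity(10, 0.45)
#' @export
apparent_viscosity <- function(diameter, hematocrit, params = rheology_params()) {
  if (any(!is.finite(diameter)) || any(diameter <= params$viscosity[["esl"]])) {
    abort("`diameter` must be finite and exceed the 1.1 um layer scale")
  }
  if (any(hematocrit < 0 | hematocrit >= 1)) {
    abort("`hematocrit` must lie in [0, 1)")
  }
  v <- params$viscosity
  D <- diameter
  H <- hematocrit
  mu45 <- v[["mu45_a"]] * exp(v[["mu45_b"]] * D) + v[["mu45_c"]] +
    v[["mu45_d"]] * exp(v[["mu45_e"]] * D^v[["mu45_f"]])
  shape <- 1 / (1 + 1e-11 * D^12)
  cc <- (0.8 + exp(-0.075 * D)) * (-1 + shape) + shape
  f <- (D / (D - v[["esl"]]))^2
  rel <- (1 + (mu45 - 1) * ((1 - H)^cc - 1) /
            ((1 - v[["href"]])^cc - 1) * f) * f
  params$plasma_viscosity * rel
}

#' Tube hematocrit from the Fahraeus effect
#'
#' Red cells travel faster than bulk blood in narrow tubes, so the
#' instantaneous (tube) hematocrit is below the flow-weighted (discharge)
#' hematocrit. Evaluates the empirical ratio
#' `HT/HD = HD + (1 - HD) * (1 + a*exp(b*D) + c*exp(d*D))`, which tends to 1
#' for large diameters.
#'
#' @inheritParams apparent_viscosity
#' @param hematocrit Discharge hematocrit(s) in `[0, 1]`.
#' @return Tube hematocrit, same length as the inputs.
#' @examples
#' fahraeus_tube_hematocrit(10, 0.45)
#' @export
fahraeus_tube_hematocrit <- function(diameter, hematocrit,
                                     params = rheology_params()) {
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    abort("`diameter` must be positive")
  }
  if (any(hematocrit < 0 | hematocrit > 1)) {
    abort("`hematocrit` must lie in [0, 1]")
  }
  f <- params$fahraeus
  ratio <- hematocrit + (1 - hematocrit) *
    (1 + f[["a"]] * exp(f[["b"]] * diameter) +
       f[["c"]] * exp(f[["d"]] * diameter))
  pmin(hematocrit * ratio, hematocrit)
}

#' Red-cell flux fraction at a diverging bifurcation
#'
#' Phase-separation (plasma skimming) law: the fraction of the feeding
#' vessel's red-cell flux entering a daughter branch is a sigmoidal function
#' of that daughter's fractional blood flow, with skew set by the
#' daughter/sibling diameter ratio and slope by the feed hematocrit and feed
#' diameter. Below a threshold fractional flow `x0/Df` the daughter receives
#' pure plasma; symmetrically above `1 - x0/Df` it receives all red cells.
#'
#' @param flow_fraction Fraction of feed blood flow entering the daughter.
#' @param d_parent,d_daughter,d_sibling Diameters (um) of the feeding vessel,
#'   the daughter considered, and the other daughter.
#' @param hematocrit Feed discharge hematocrit.
#' @param params A [rheology_params()].
#' @return Fraction of feed red-cell flux entering the daughter, in `[0, 1]`.
#' @examples
#' phase_separation(0.3, d_parent = 20, d_daughter = 12, d_sibling = 16,
#'                  hematocrit = 0.45)
#' @export
phase_separation <- function(flow_fraction, d_parent, d_daughter, d_sibling,
                             hematocrit, params = rheology_params()) {
  stopifnot(all(flow_fraction >= 0 & flow_fraction <= 1),
            all(d_parent > 0), all(d_daughter > 0), all(d_sibling > 0),
            all(hematocrit >= 0 & hematocrit <= 1))
  p <- params$phase_separation
  x0 <- p[["x0"]] / d_parent
  a <- p[["a"]] * log(d_daughter / d_sibling) / d_parent
  b <- 1 + p[["b"]] * (1 - hematocrit) / d_parent
  x <- (flow_fraction - x0) / (1 - 2 * x0)
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  out <- 1 / (1 + exp(-(a + b * log(x / (1 - x)))))
  out[flow_fraction <= x0] <- 0
  out[flow_fraction >= 1 - x0] <- 1
  pmin(pmax(out, 0), 1)
}
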