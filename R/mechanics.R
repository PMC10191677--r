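# Closed-form cantilever mechanics and tensile-curve analysis.
#
# The posts are modelled as end-loaded Euler-Bernoulli cantilevers in the
# small-deflection regime, consistent with the symmetric, linear
# force-deflection behaviour of the device. Poisson's ratio and density are
# carried on the beam specification for fidelity to the physical material
# model but do not enter the statics.

#' Specify a cantilever beam
#'
#' @param E_pa Young's modulus, Pa (e.g. 1.33e6 for the device elastomer).
#' @param L_m Beam length, m.
#' @param section `"rectangular"` or `"circular"`.
#' @param width_m,thickness_m Rectangular section dimensions, m (thickness is
#'   measured along the bending direction).
#' @param radius_m Circular section radius, m.
#' @param poisson Poisson's ratio (recorded; unused by the statics). The
#'   device elastomer is nearly incompressible (0.499).
#' @param density Density, kg/m^3 (recorded; unused by the statics).
#' @return A `beam_spec`.
#' @export
beam_spec <- function(E_pa, L_m, section = c("rectangular", "circular"),
                      width_m = NULL, thickness_m = NULL, radius_m = NULL,
                      poisson = 0.499, density = 1120) {
  section <- match.arg(section)
  if (!is.finite(E_pa) || E_pa <= 0 || !is.finite(L_m) || L_m <= 0)
    mp_stop("E_pa and L_m must be > 0", "input_error")
  if (poisson < 0 || poisson >= 0.5 + 1e-6)
    mp_stop("poisson must lie in [0, 0.5]", "input_error")
  if (section == "rectangular") {
    if (is.null(width_m) || is.null(thickness_m) ||
        width_m <= 0 || thickness_m <= 0)
      mp_stop("rectangular section needs width_m and thickness_m > 0",
              "input_error")
  } else if (is.null(radius_m) || radius_m <= 0) {
    mp_stop("circular section needs radius_m > 0", "input_error")
  }
  structure(list(E_pa = E_pa, L_m = L_m, section = section,
                 width_m = width_m, thickness_m = thickness_m,
                 radius_m = radius_m, poisson = poisson, density = density),
            class = "beam_spec")
}

second_moment <- function(beam) {
  if (beam$section == "rectangular") beam$width_m * beam$thickness_m^3 / 12
  else pi * beam$radius_m^4 / 4
}

#' Cantilever spring constant
#'
#' `k = 3 E I / L^3` for an end-loaded cantilever, with
#' `I = w t^3 / 12` (rectangular) or `pi r^4 / 4` (circular). A spring
#' constant of x N/m equals x uN/um (1 N/m = 10^6 uN per 10^6 um), so the
#' returned value reads identically in both unit systems.
#'
#' @param beam A [beam_spec()].
#' @return Spring constant in uN/um (numerically equal to N/m).
#' @export
beam_spring_constant <- function(beam) {
  stopifnot(inherits(beam, "beam_spec"))
  3 * beam$E_pa * second_moment(beam) / beam$L_m^3
}

#' Cantilever tip deflection under an end load
#'
#' `delta = F L^3 / (3 E I)`; exact inverse of [beam_spring_constant()].
#'
#' @param force_un End load, uN.
#' @param beam A [beam_spec()].
#' @return Tip deflection, um.
#' @export
tip_deflection <- function(force_un, beam) {
  force_un / beam_spring_constant(beam)
}

#' Build a tensile curve object
#' @param strain Non-decreasing dimensionless strain samples starting at 0.
#' @param stress_pa Stress samples, Pa.
#' @param failure_index Optional index of the tear; detected from a > 20%
#'   stress drop from the running maximum when absent.
#' @return A `tensile_curve`.
#' @export
tensile_curve <- function(strain, stress_pa, failure_index = NULL) {
  if (length(strain) != length(stress_pa))
    mp_stop("strain and stress must have equal length", "input_error")
  if (length(strain) < 2L || strain[1] != 0 || is.unsorted(strain))
    mp_stop("strain must be non-decreasing and start at 0", "input_error")
  structure(list(strain = strain, stress_pa = stress_pa,
                 failure_index = failure_index),
            class = "tensile_curve")
}

#' Young's modulus and ultimate tensile strain from a tensile curve
#'
#' The modulus is the least-squares slope of stress on strain over the
#' small-strain linear region (default strain <= 0.1, the standard modulus
#' convention for elastomers whose curves stiffen beyond); the ultimate
#' tensile strain is the strain at failure. When no failure index is given,
#' failure is the last sample before the first > 20% drop from the running
#' stress maximum (or the final sample if no tear is seen).
#'
#' @param curve A [tensile_curve()] or a data frame with columns `strain` and
#'   `stress_pa`.
#' @param linear_region Upper strain bound of the fitted linear region.
#' @return List with `E_pa` and `ultimate_strain`.
#' @export
analyze_tensile_curve <- function(curve, linear_region = 0.1) {
  if (is.data.frame(curve))
    curve <- tensile_curve(curve$strain, curve$stress_pa)
  stopifnot(inherits(curve, "tensile_curve"))
  sel <- curve$strain <= linear_region
  if (sum(sel) < 3L)
    mp_stop(sprintf("only %d samples at strain <= %g; need >= 3 for the fit",
                    sum(sel), linear_region), "analysis_error")
  fit <- stats::lm(stress ~ strain,
                   data = data.frame(strain = curve$strain[sel],
                                     stress = curve$stress_pa[sel]))
  fi <- curve$failure_index
  if (is.null(fi)) {
    run_max <- cummax(curve$stress_pa)
    # a tear is a > 20% drop from the running maximum once the sample is
    # meaningfully loaded (guards against noise around zero stress)
    drop <- which(curve$stress_pa < 0.8 * run_max &
                    run_max > 0.25 * max(curve$stress_pa))
    fi <- if (length(drop) && drop[1] > 1L) drop[1] - 1L
          else length(curve$strain)
  }
  list(E_pa = unname(stats::coef(fit)["strain"]),
       ultimate_strain = curve$strain[fi])
}

#' Simulate a tensile test with known material truth
#'
#' Linear loading ramp `stress = E * strain` with additive Gaussian noise,
#' followed by a tear (sharp stress drop) at the ultimate strain. Useful as
#' a ground-truthed input for [analyze_tensile_curve()].
#'
#' @param E_pa True modulus, Pa.
#' @param ultimate_strain True strain at failure.
#' @param n Samples up to failure.
#' @param noise_sd Stress noise, Pa.
#' @param seed Integer seed.
#' @return A `tensile_curve` (without a recorded failure index, so detection
#'   is exercised).
#' @export
simulate_tensile_curve <- function(E_pa, ultimate_strain, n = 100L,
                                   noise_sd = 0, seed = 1L) {
  with_seed(seed, {
    strain <- seq(0, ultimate_strain, length.out = n)
    stress <- E_pa * strain + stats::rnorm(n, sd = noise_sd)
    # post-tear samples: stress collapses
    strain <- c(strain, ultimate_strain * c(1.001, 1.002))
    stress <- c(stress, 0.1 * E_pa * ultimate_strain,
                0.05 * E_pa * ultimate_strain)
    tensile_curve(strain, stress)
  })
}
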