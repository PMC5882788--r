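# Closed-form isopycnic-centrifugation physics shared by all simulation
# stages: the linear G+C / buoyant-density relation, the equilibrium
# Gaussian width of a DNA fragment band, the radial position of an
# isoconcentration surface, the diffusive-boundary-layer fraction, and the
# buoyant-density shift caused by heavy-isotope incorporation.

#' Physical constants for equilibrium band-width calculations
#'
#' Constants entering the closed form for the standard deviation of the
#' Gaussian buoyant-density (BD) distribution of a homogeneous set of DNA
#' fragments at sedimentation equilibrium in a CsCl gradient:
#' \deqn{\sigma = \sqrt{\rho R T / (\beta^2 G M_C \ell)}}
#' where \eqn{\rho} is the fragment BD and \eqn{\ell} its length in bp.
#'
#' Defaults follow the standard CsCl literature values; none of them is
#' universal across gradient media, so all are overridable.
#'
#' @param R universal gas constant (erg mol^-1 K^-1).
#' @param T temperature (K); default 293.15 K (20 degrees C).
#' @param beta proportionality constant for aqueous CsCl.
#' @param G buoyancy factor (dimensionless, CsCl).
#' @param M_C molecular weight of a DNA base pair (g mol^-1 bp^-1).
#' @return object of class `physics_constants`.
#' @export
#' @examples
#' pc <- physics_constants()
#' fragment_sigma(1.70, 4000, pc)
physics_constants <- function(R = 8.3145e7, T = 293.15, beta = 1.14e9,
                              G = 7.87e-10, M_C = 882) {
  vals <- c(R = R, T = T, beta = beta, G = G, M_C = M_C)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physics constants must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "physics_constants")
}

#' Rotor geometry and run conditions
#'
#' Describes the centrifuge rotor and run used to map buoyant density to
#' radial position.  Defaults describe a small vertical rotor run at
#' 55,000 rpm with an average gradient density of 1.70 g ml^-1, typical of
#' amplicon-era DNA-SIP work.
#'
#' @param beta0 gradient-medium coefficient (CsCl: ~1.14e9 in cgs units).
#' @param rpm rotor speed (revolutions per minute); converted to
#'   `omega` (rad s^-1) internally.
#' @param r_c reference radius (cm) at which density equals `rho_m`.
#' @param rho_m density at the reference radius (g ml^-1).
#' @param rotor_type `"vertical"` or `"fixed-angle"`.
#' @param tube_length,tube_radius,tube_angle tube dimensions (cm, cm, degrees
#'   from vertical); recorded for geometry-resolved smearing modes.
#' @return object of class `rotor_geometry`.
#' @export
rotor_geometry <- function(beta0 = 1.14e9, rpm = 55000, r_c = 4.0,
                           rho_m = 1.70, rotor_type = c("vertical", "fixed-angle"),
                           tube_length = 4.0, tube_radius = 0.65,
                           tube_angle = 0) {
  rotor_type <- match.arg(rotor_type)
  omega <- rpm * 2 * pi / 60
  if (omega <= 0 || r_c <= 0)
    stop("omega and r_c must be positive", call. = FALSE)
  structure(list(beta0 = beta0, omega = omega, rpm = rpm, r_c = r_c,
                 rho_m = rho_m, rotor_type = rotor_type,
                 tube_length = tube_length, tube_radius = tube_radius,
                 tube_angle = tube_angle),
            class = "rotor_geometry")
}

# Registry of maximum BD shifts at 100 atom % excess, g ml^-1.  New isotopes
# (2H, 18O, ...) can be registered via `isotope_spec(..., I_max = )`.
.isotope_registry <- list(`13C` = 0.036, `15N` = 0.016)

#' Isotope specification
#'
#' The maximum buoyant-density shift `I_max` reached at 100 atom % excess of
#' the heavy isotope.  Fully labeled DNA shifts by 0.036 g ml^-1 for 13C and
#' 0.016 g ml^-1 for 15N; intermediate labeling scales linearly.
#'
#' @param isotope isotope name; `"13C"` and `"15N"` are built in.
#' @param I_max optional override / registration of the maximum shift
#'   (g ml^-1) for isotopes not in the registry.
#' @return object of class `isotope_spec` with fields `isotope`, `I_max`.
#' @export
#' @examples
#' isotope_bd_shift(100, isotope_spec("13C"))  # 0.036
isotope_spec <- function(isotope = "13C", I_max = NULL) {
  if (is.null(I_max)) {
    if (!isotope %in% names(.isotope_registry))
      stop("unknown isotope '", isotope, "'; supply I_max to register it",
           call. = FALSE)
    I_max <- .isotope_registry[[isotope]]
  }
  stopifnot(is.numeric(I_max), I_max > 0)
  structure(list(isotope = isotope, I_max = I_max), class = "isotope_spec")
}

#' Diffusive-boundary-layer parameters
#'
#' The fraction of a taxon's DNA entrained in the diffusive boundary layer
#' along the tube wall is modeled as `D = abundance * gamma + alpha`: a
#' baseline `alpha` plus an abundance-proportional term weighted by `gamma`.
#' Entrained DNA ends up at non-equilibrium positions after gradient
#' reorientation, which is why abundant taxa are detected in every fraction
#' of real gradients.
#'
#' @param gamma weight of taxon relative abundance (dimensionless, >= 0).
#' @param alpha baseline boundary-layer fraction (dimensionless, >= 0).
#' @return object of class `dbl_params`.
#' @export
dbl_params <- function(gamma = 1.0, alpha = 1e-4) {
  if (gamma < 0 || alpha < 0)
    stop("gamma and alpha must be non-negative", call. = FALSE)
  structure(list(gamma = gamma, alpha = alpha), class = "dbl_params")
}

#' Buoyant density of DNA from its G+C content
#'
#' Empirical linear relation for CsCl gradients:
#' `BD = 0.098 * GC + 1.66` (g ml^-1), with `GC` the mole fraction of G+C.
#'
#' @param gc G+C mole fraction in `[0, 1]` (vectorized).
#' @return buoyant density (g ml^-1).
#' @seealso [bd_to_gc()] for the inverse.
#' @export
#' @examples
#' gc_to_bd(0.5)  # 1.709
gc_to_bd <- function(gc) {
  assert_scalar_in(gc, 0, 1, "gc")
  0.098 * gc + 1.66
}

#' G+C content of DNA from its buoyant density
#'
#' Inverse of [gc_to_bd()].  Values outside the physical range
#' `[1.66, 1.758]` g ml^-1 error unless `clamp = TRUE`.
#'
#' @param bd buoyant density (g ml^-1, vectorized).
#' @param clamp clip out-of-range densities to the valid interval instead of
#'   erroring.
#' @return G+C mole fraction in `[0, 1]`.
#' @export
bd_to_gc <- function(bd, clamp = FALSE) {
  if (clamp) bd <- pmin(pmax(bd, 1.66), 1.758)
  assert_scalar_in(bd, 1.66, 1.758, "bd")
  (bd - 1.66) / 0.098
}

#' Equilibrium band width of a DNA fragment
#'
#' Standard deviation (g ml^-1) of the Gaussian buoyant-density distribution
#' of a homogeneous pool of DNA fragments at sedimentation equilibrium.
#' Scales as `1/sqrt(length)`: long fragments form tight bands, short
#' fragments diffuse bands.
#'
#' @param bd fragment buoyant density (g ml^-1).
#' @param length fragment length (bp); must be >= 1.
#' @param constants a [physics_constants()] object.
#' @return sigma (g ml^-1); vectorized over `bd` and `length`.
#' @export
fragment_sigma <- function(bd, length, constants = physics_constants()) {
  if (any(length < 1)) stop("fragment length must be >= 1 bp", call. = FALSE)
  if (any(bd <= 0)) stop("bd must be positive", call. = FALSE)
  with(constants, sqrt(bd * R * T / (beta^2 * G * M_C * length)))
}

#' Buoyant-density shift from heavy-isotope incorporation
#'
#' Linear in atom % excess: `shift = I_max * A / 100`.
#'
#' @param atom_pct_excess atom % excess in `[0, 100]` (vectorized).
#' @param isotope an [isotope_spec()].
#' @return BD shift (g ml^-1).
#' @export
isotope_bd_shift <- function(atom_pct_excess, isotope = isotope_spec("13C")) {
  assert_scalar_in(atom_pct_excess, 0, 100, "atom_pct_excess")
  isotope$I_max * atom_pct_excess / 100
}

#' Radial position of an isoconcentration surface
#'
#' At equilibrium the density profile of the gradient follows
#' `rho(x) = rho_m + omega^2 (x^2 - r_c^2) / (2 beta0)`, so the radius at
#' which a given buoyant density is found is
#' `x = sqrt((bd - rho_m) * 2 * beta0 / omega^2 + r_c^2)` (cm).
#'
#' @param bd buoyant density (g ml^-1); must be >= `rotor$rho_m`.
#' @param rotor a [rotor_geometry()].
#' @return distance from the axis of rotation (cm).
#' @export
bd_to_radius <- function(bd, rotor = rotor_geometry()) {
  if (any(bd < rotor$rho_m))
    stop("bd below the density at the reference radius", call. = FALSE)
  sqrt((bd - rotor$rho_m) * 2 * rotor$beta0 / rotor$omega^2 + rotor$r_c^2)
}

#' Buoyant density at a given radius (inverse of [bd_to_radius()])
#' @param x radius (cm).
#' @param rotor a [rotor_geometry()].
#' @return buoyant density (g ml^-1).
#' @export
radius_to_bd <- function(x, rotor = rotor_geometry()) {
  rotor$rho_m + rotor$omega^2 * (x^2 - rotor$r_c^2) / (2 * rotor$beta0)
}

#' Fraction of a taxon's DNA in the diffusive boundary layer
#'
#' `D = abundance * gamma + alpha`, clipped to `[0, 1]`.
#'
#' @param abundance pre-fractionation relative abundance in `[0, 1]`
#'   (vectorized).
#' @param params a [dbl_params()].
#' @return boundary-layer fraction in `[0, 1]`.
#' @export
dbl_fraction <- function(abundance, params = dbl_params()) {
  assert_scalar_in(abundance, 0, 1, "abundance")
  pmin(pmax(abundance * params$gamma + params$alpha, 0), 1)
}
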