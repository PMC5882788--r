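# Stage 1 of the simulation: per-taxon 2-D (length x G+C) kernel density
# estimate of the fragment pool, Monte-Carlo integration into a 1-D
# buoyant-density (BD) profile, diffusive-boundary-layer (DBL) smearing,
# and isotope incorporation.
#
# A BD profile is represented semi-analytically: the equilibrium component
# is a Gaussian KDE (kernel centers = Monte-Carlo BD draws, common
# bandwidth), the DBL component is a uniform over the gradient span with
# mixture weight D, and isotope incorporation is a rigid translation of the
# equilibrium component only (entrained boundary-layer DNA sits at
# non-equilibrium positions regardless of label).  This makes per-fraction
# probability masses exact Gaussian-CDF sums rather than quadrature.

#' Fit a 2-D kernel density over fragment (length, G+C)
#'
#' Gaussian product-kernel KDE with per-dimension Scott's-rule bandwidths
#' (`sd * n^(-1/6)`).  The KDE is stored as the fragment sample plus
#' bandwidths; resampling draws a fragment at random and adds kernel noise.
#'
#' @param frags a `fragment_set` with at least 30 fragments.
#' @param bandwidth optional length-2 numeric (length bp, gc) overriding
#'   Scott's rule.
#' @return object of class `length_gc_kde`.
#' @export
fit_length_gc_kde <- function(frags, bandwidth = NULL) {
  stopifnot(inherits(frags, "fragment_set"))
  n <- length(frags$lengths)
  if (n < 30) stop("need >= 30 fragments to fit the 2-D KDE", call. = FALSE)
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::sd(frags$lengths), stats::sd(frags$gc)) * n^(-1 / 6)
    bandwidth[bandwidth == 0 | !is.finite(bandwidth)] <- 1e-12
  }
  structure(list(taxon_id = frags$taxon_id,
                 data = cbind(length = frags$lengths, gc = frags$gc),
                 bandwidth = bandwidth),
            class = "length_gc_kde")
}

#' Resample (length, G+C) pairs from a fitted 2-D KDE
#'
#' @param kde a `length_gc_kde`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return matrix with columns `length` (>= 1) and `gc` (clipped to
#'   `[0, 1]`).
#' @export
resample_length_gc <- function(kde, n, seed = NULL) {
  with_seed(seed, {
    i <- sample.int(nrow(kde$data), n, replace = TRUE)
    len <- kde$data[i, "length"] + stats::rnorm(n, 0, kde$bandwidth[1])
    gc <- kde$data[i, "gc"] + stats::rnorm(n, 0, kde$bandwidth[2])
    cbind(length = pmax(len, 1), gc = pmin(pmax(gc, 0), 1))
  })
}

new_bd_profile <- function(taxon_id, centers, bw, stage = "equilibrium",
                           dbl_frac = 0, span = c(1.67, 1.78), shift = 0,
                           n_mc = length(centers)) {
  structure(list(taxon_id = taxon_id, centers = centers, bw = bw,
                 stage = stage, dbl_frac = dbl_frac, span = span,
                 shift = shift, n_mc = n_mc),
            class = "bd_profile")
}

#' @export
print.bd_profile <- function(x, ...) {
  cat(sprintf("<bd_profile> %s [%s]: mean BD %.4f g/ml, D=%.3g, shift=%+.4f\n",
              x$taxon_id, x$stage, profile_mean(x), x$dbl_frac, x$shift))
  invisible(x)
}

#' Build the equilibrium buoyant-density profile of a taxon
#'
#' Monte-Carlo integration of the fragment pool: draw `n_mc`
#' (length, G+C) pairs from the 2-D KDE; for each, the fragment band is
#' Gaussian with mean [gc_to_bd()] and standard deviation
#' [fragment_sigma()]; draw one BD value per fragment and fit a 1-D
#' Gaussian KDE (Scott's rule) to the pooled draws.
#'
#' @param kde a `length_gc_kde` from [fit_length_gc_kde()].
#' @param n_mc Monte-Carlo replicates (default 1e5; >= 1e3 required).
#'   Reduced values trade profile smoothness for speed.
#' @param constants a [physics_constants()].
#' @param span gradient BD span (g ml^-1) retained with the profile for
#'   later DBL smearing.
#' @param bandwidth optional 1-D KDE bandwidth override (g ml^-1).
#' @param seed integer seed.
#' @return a `bd_profile` with stage `"equilibrium"`.
#' @export
build_bd_profile <- function(kde, n_mc = 1e5,
                             constants = physics_constants(),
                             span = c(1.67, 1.78), bandwidth = NULL,
                             seed = NULL) {
  if (n_mc < 1e3) stop("n_mc must be >= 1000", call. = FALSE)
  with_seed(seed, {
    lg <- resample_length_gc(kde, n_mc)
    mu <- gc_to_bd(lg[, "gc"])
    sg <- fragment_sigma(mu, lg[, "length"], constants)
    bd <- stats::rnorm(n_mc, mu, sg)
    bw <- bandwidth %||% (stats::sd(bd) * n_mc^(-1 / 5))
    if (!is.finite(bw) || bw <= 0) bw <- 1e-6
    new_bd_profile(kde$taxon_id, bd, bw, span = span, n_mc = n_mc)
  })
}

#' Apply diffusive-boundary-layer smearing to a profile
#'
#' Replaces the equilibrium density `f` by the mixture
#' `(1 - D) f + D Uniform(span)` where `D = dbl_fraction(abundance,
#' params)`: the entrained fraction of the taxon's DNA is spread uniformly
#' across the whole gradient.
#'
#' @param profile an equilibrium-stage `bd_profile`.
#' @param params a [dbl_params()].
#' @param abundance the taxon's pre-fractionation relative abundance.
#' @param span optional override of the smearing span (g ml^-1).
#' @return a `bd_profile` with stage `"+DBL"`.
#' @export
apply_dbl <- function(profile, params = dbl_params(), abundance,
                      span = NULL) {
  if (profile$stage != "equilibrium")
    stop("DBL smearing must be applied to an equilibrium profile", call. = FALSE)
  profile$dbl_frac <- dbl_fraction(abundance, params)
  if (!is.null(span)) profile$span <- span
  profile$stage <- "+DBL"
  profile
}

#' Apply isotope incorporation to a profile
#'
#' With the default point-mass intra-population model the equilibrium
#' component is translated by [isotope_bd_shift()]; the uniform DBL
#' component is left in place.  A non-degenerate intra-population model
#' (per-fragment atom % draws) yields the Monte-Carlo convolution of the
#' profile with the shift distribution.
#'
#' @param profile a `bd_profile` at stage `"+DBL"` or `"equilibrium"`.
#' @param taxon_atom_pct the taxon's atom % excess in `[0, 100]`.
#' @param isotope an [isotope_spec()].
#' @param intra optional function `n -> atom %` draws describing
#'   intra-population variation; `NULL` = point mass at `taxon_atom_pct`.
#' @param seed integer seed (used only with a non-degenerate `intra`).
#' @return a `bd_profile` with stage `"+incorporation"`.
#' @export
apply_incorporation <- function(profile, taxon_atom_pct,
                                isotope = isotope_spec("13C"),
                                intra = NULL, seed = NULL) {
  if (!profile$stage %in% c("+DBL", "equilibrium"))
    stop("incorporation must follow the equilibrium/+DBL stages", call. = FALSE)
  assert_scalar_in(taxon_atom_pct, 0, 100, "taxon_atom_pct")
  if (is.null(intra)) {
    profile$shift <- profile$shift + isotope_bd_shift(taxon_atom_pct, isotope)
  } else {
    draws <- with_seed(seed, intra(length(profile$centers)))
    assert_scalar_in(draws, 0, 100, "intra draws")
    profile$centers <- profile$centers + isotope_bd_shift(draws, isotope)
  }
  profile$stage <- "+incorporation"
  profile
}

#' Probability density of a BD profile
#' @param profile a `bd_profile`.
#' @param x buoyant densities (g ml^-1) at which to evaluate.
#' @return density values.
#' @export
profile_pdf <- function(profile, x) {
  D <- profile$dbl_frac
  kde <- vapply(x, function(xi)
    mean(stats::dnorm(xi, profile$centers + profile$shift, profile$bw)),
    numeric(1))
  u <- stats::dunif(x, profile$span[1], profile$span[2])
  (1 - D) * kde + D * u
}

#' Probability mass of a BD profile in `[lo, hi)` intervals
#'
#' Exact under the KDE representation (Gaussian CDF sums plus the uniform
#' overlap); used to bin fragments into gradient fractions.
#'
#' @param profile a `bd_profile`.
#' @param lo,hi interval bounds (g ml^-1), vectorized.
#' @return per-interval probability mass.
#' @export
profile_mass <- function(profile, lo, hi) {
  c0 <- profile$centers + profile$shift
  # outer() over interval bounds x kernel centers
  p_hi <- colMeans(matrix(stats::pnorm(outer(c0, hi, function(c, b) (b - c) / profile$bw)),
                          nrow = length(c0)))
  p_lo <- colMeans(matrix(stats::pnorm(outer(c0, lo, function(c, b) (b - c) / profile$bw)),
                          nrow = length(c0)))
  D <- profile$dbl_frac
  w <- profile$span[2] - profile$span[1]
  ov <- pmax(pmin(hi, profile$span[2]) - pmax(lo, profile$span[1]), 0)
  (1 - D) * (p_hi - p_lo) + D * ov / w
}

#' Mean buoyant density of a profile
#' @param profile a `bd_profile`.
#' @return mean BD (g ml^-1).
#' @export
profile_mean <- function(profile) {
  D <- profile$dbl_frac
  (1 - D) * mean(profile$centers + profile$shift) + D * mean(profile$span)
}

#' Sample buoyant densities from a profile
#' @param profile a `bd_profile`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of BD values.
#' @export
sample_bd <- function(profile, n, seed = NULL) {
  with_seed(seed, {
    from_dbl <- stats::runif(n) < profile$dbl_frac
    out <- numeric(n)
    n_k <- sum(!from_dbl)
    if (n_k) {
      i <- sample.int(length(profile$centers), n_k, replace = TRUE)
      out[!from_dbl] <- profile$centers[i] + profile$shift +
        stats::rnorm(n_k, 0, profile$bw)
    }
    if (any(from_dbl))
      out[from_dbl] <- stats::runif(sum(from_dbl), profile$span[1],
                                    profile$span[2])
    out
  })
}
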