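# Hard-disk representation of a crowded membrane.
#
# Units: lengths nm, areas nm^2, areal number density (concentration) nm^-2.
# Abundances are arbitrary nonnegative weights, normalized internally.

# SPT for disks loses accuracy approaching close packing; warn above this.
.PHI_SPT_WARN <- 0.78

#' Construct a hard-disk crowder mixture
#'
#' A `crowder_mixture` describes the crowding membrane proteins as a finite
#' discrete mixture of hard disks: in-plane radii, relative abundances, and a
#' total areal number density. Either the density `concentration` or the
#' protein `area_fraction` may be given; the other is derived from the
#' second radius moment.
#'
#' @param radii Numeric vector of disk radii in nm, each > 0.
#' @param abundances Relative weights (unitless, >= 0, not all zero). Default:
#'   equal weights. Normalized internally; any common scale factor is
#'   irrelevant.
#' @param concentration Total areal number density c in nm^-2 (>= 0).
#' @param area_fraction Protein area fraction phi = c * pi * <r^2>, in `[0, 1)`.
#'   Exactly one of `concentration` and `area_fraction` must be supplied.
#' @param delta2 Optional override for the relative radius variance
#'   delta^2 = (<r^2> - <r>^2) / <r>^2 used by the scaled-particle formulas.
#'   By default delta^2 is computed from `radii` and `abundances`; supplying a
#'   value lets a nominally uniform mixture carry the size variability of an
#'   underlying distribution (e.g. a transmembrane-helix census).
#'
#' @return An object of class `crowder_mixture` with elements `radii`,
#'   `weights` (normalized abundances), `concentration`, `area_fraction`,
#'   and `delta2_override`.
#'
#' @details Construction fails for area fractions >= 1 (unphysical packing)
#'   and warns above phi = 0.78, where scaled-particle theory for disks is
#'   known to degrade near the close-packing limit.
#'
#' @examples
#' # the MscL worked example: uniform 1 nm crowders covering half the membrane
#' m <- crowder_mixture(radii = 1, area_fraction = 0.5)
#' m$concentration # 0.5 / pi
#'
#' # a binary mixture at a given number density
#' crowder_mixture(radii = c(0.8, 2.1), abundances = c(3, 1),
#'                 concentration = 0.05)
#' @export
crowder_mixture <- function(radii, abundances = NULL, concentration = NULL,
                            area_fraction = NULL, delta2 = NULL) {
  radii <- as.numeric(radii)
  if (length(radii) < 1L || anyNA(radii) || any(radii <= 0)) {
    stop("`radii` must be a non-empty numeric vector of positive radii (nm)",
         call. = FALSE)
  }
  if (is.null(abundances)) abundances <- rep(1, length(radii))
  abundances <- as.numeric(abundances)
  if (length(abundances) != length(radii) || anyNA(abundances) ||
      any(abundances < 0) || sum(abundances) == 0) {
    stop("`abundances` must be nonnegative weights, not all zero, one per radius",
         call. = FALSE)
  }
  if (!is.null(delta2)) {
    delta2 <- as.numeric(delta2)
    if (length(delta2) != 1L || is.na(delta2) || delta2 < 0) {
      stop("`delta2` override must be a single nonnegative number", call. = FALSE)
    }
  }
  w <- abundances / sum(abundances)
  mean_r2 <- sum(w * radii^2)

  if (is.null(concentration) == is.null(area_fraction)) {
    stop("supply exactly one of `concentration` and `area_fraction`",
         call. = FALSE)
  }
  if (is.null(concentration)) {
    concentration <- concentration_for_fraction(area_fraction, mean_r2)
  } else {
    if (length(concentration) != 1L || is.na(concentration) || concentration < 0) {
      stop("`concentration` must be a single nonnegative density (nm^-2)",
           call. = FALSE)
    }
    area_fraction <- area_fraction(concentration, mean_r2)
  }
  if (area_fraction > .PHI_SPT_WARN) {
    warning(sprintf(
      "area fraction %.3f exceeds %.2f; scaled-particle theory is inaccurate near close packing",
      area_fraction, .PHI_SPT_WARN), call. = FALSE)
  }

  structure(
    list(radii = radii, weights = w, concentration = concentration,
         area_fraction = area_fraction, delta2_override = delta2),
    class = "crowder_mixture"
  )
}

#' Uniform-crowder convenience constructor
#'
#' Single-species special case of [crowder_mixture()]: all crowders share one
#' radius `r`, as in the worked MscL example (r = 1 nm, phi = 0.5).
#'
#' @param r Crowder radius in nm.
#' @inheritParams crowder_mixture
#' @return A `crowder_mixture`.
#' @export
uniform_mixture <- function(r, concentration = NULL, area_fraction = NULL,
                            delta2 = NULL) {
  crowder_mixture(radii = r, abundances = 1, concentration = concentration,
                  area_fraction = area_fraction, delta2 = delta2)
}

#' @export
print.crowder_mixture <- function(x, ...) {
  mom <- mixture_moments(x)
  cat("Hard-disk crowder mixture\n")
  cat(sprintf("  species:        %d\n", length(x$radii)))
  cat(sprintf("  <r>:            %.4g nm\n", mom$mean_r))
  cat(sprintf("  <r^2>:          %.4g nm^2\n", mom$mean_r2))
  cat(sprintf("  delta^2:        %.4g%s\n", mom$delta2,
              if (!is.null(x$delta2_override)) " (override)" else ""))
  cat(sprintf("  concentration:  %.4g nm^-2\n", x$concentration))
  cat(sprintf("  area fraction:  %.4g\n", x$area_fraction))
  invisible(x)
}

#' Abundance-weighted radius moments of a crowder mixture
#'
#' @param mixture A [crowder_mixture()].
#' @return A list with `mean_r` (nm), `mean_r2` (nm^2) and `delta2`, the
#'   relative radius variance (<r^2> - <r>^2) / <r>^2 (or the mixture's
#'   override if one was set).
#' @examples
#' mixture_moments(crowder_mixture(c(1, 3), concentration = 0.01))
#' # mean_r 2, mean_r2 5, delta2 0.25
#' @export
mixture_moments <- function(mixture) {
  stopifnot(inherits(mixture, "crowder_mixture"))
  m1 <- sum(mixture$weights * mixture$radii)
  m2 <- sum(mixture$weights * mixture$radii^2)
  d2 <- max(0, (m2 - m1^2) / m1^2) # clamp tiny negative round-off
  if (!is.null(mixture$delta2_override)) d2 <- mixture$delta2_override
  list(mean_r = m1, mean_r2 = m2, delta2 = d2)
}

#' Protein area fraction from density and mean squared radius
#'
#' phi = c * pi * <r^2>: the fraction of the membrane plane covered by
#' protein disks.
#'
#' @param concentration Areal number density c in nm^-2 (>= 0).
#' @param mean_r2 Second radius moment <r^2> in nm^2.
#' @return phi, in `[0, 1)`. Errors for phi >= 1 (unphysical packing).
#' @export
area_fraction <- function(concentration, mean_r2) {
  if (concentration < 0) stop("`concentration` must be >= 0", call. = FALSE)
  phi <- concentration * pi * mean_r2
  if (phi >= 1) {
    stop(sprintf("area fraction %.3f >= 1: unphysical packing", phi),
         call. = FALSE)
  }
  phi
}

#' Crowder density that realizes a given area fraction
#'
#' Inverse of [area_fraction()]: c = phi / (pi * <r^2>). Round-trips with
#' [area_fraction()] to machine precision.
#'
#' @param phi Target area fraction, in `[0, 1)`.
#' @param mean_r2 Second radius moment <r^2> in nm^2 (> 0).
#' @return Areal number density in nm^-2.
#' @export
concentration_for_fraction <- function(phi, mean_r2) {
  if (length(phi) != 1L || is.na(phi) || phi < 0 || phi >= 1) {
    stop("`phi` must lie in [0, 1)", call. = FALSE)
  }
  if (mean_r2 <= 0) stop("`mean_r2` must be > 0", call. = FALSE)
  phi / (pi * mean_r2)
}

#' Area fraction from the protein-to-lipid mass ratio
#'
#' Membrane inventories are often reported as a protein:lipid mass ratio m
#' (typically 1-2.5). Assuming transmembrane domains make up a fraction f of
#' the membrane-protein mass (about one half) and have roughly the lipid mass
#' density, the in-plane protein area fraction is
#' phi = f * m / (f * m + 1).
#'
#' @param protein_lipid_mass_ratio Protein:lipid mass ratio m (>= 0).
#' @param tm_mass_fraction Fraction f of protein mass in the transmembrane
#'   domain, in `[0, 1]`. Default 0.5.
#' @return Area fraction in `[0, 1)`; monotone increasing in both arguments.
#' @examples
#' mass_ratio_to_area_fraction(1)    # ~0.33
#' mass_ratio_to_area_fraction(2.5)  # ~0.56
#' @export
mass_ratio_to_area_fraction <- function(protein_lipid_mass_ratio,
                                        tm_mass_fraction = 0.5) {
  m <- protein_lipid_mass_ratio
  f <- tm_mass_fraction
  if (any(m < 0)) stop("mass ratio must be >= 0", call. = FALSE)
  if (any(f < 0) || any(f > 1)) {
    stop("`tm_mass_fraction` must lie in [0, 1]", call. = FALSE)
  }
  f * m / (f * m + 1)
}

#' Serialize a mixture to a plain configuration list
#'
#' @param mixture A [crowder_mixture()].
#' @return A named list (`radii`, `abundances`, `concentration`, and
#'   optionally `delta2`) suitable for YAML/JSON serialization;
#'   [mixture_from_config()] inverts it.
#' @export
mixture_to_config <- function(mixture) {
  stopifnot(inherits(mixture, "crowder_mixture"))
  cfg <- list(radii = mixture$radii, abundances = mixture$weights,
              concentration = mixture$concentration)
  if (!is.null(mixture$delta2_override)) cfg$delta2 <- mixture$delta2_override
  cfg
}

#' Build a mixture from a plain configuration list
#'
#' Accepts the mapping written by [mixture_to_config()]: `radii`, optional
#' `abundances`, exactly one of `concentration` / `area_fraction`, and an
#' optional `delta2` override.
#'
#' @param config A named list.
#' @return A [crowder_mixture()].
#' @export
mixture_from_config <- function(config) {
  crowder_mixture(radii = config$radii,
                  abundances = config$abundances,
                  concentration = config$concentration,
                  area_fraction = config$area_fraction,
                  delta2 = config$delta2)
}
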