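# Crowding-induced entropic tensions.
#
# Two levels of theory:
#   * ideal gas — crowders do not interact with each other; the surface
#     tension is the 2D ideal-gas law sigma = c and the line tension
#     tau = c<r> comes from the exclusion annulus of width <r>.
#   * scaled-particle theory (SPT) for hard-disk mixtures — accounts for
#     overlap of exclusion zones; accurate up to high packing fractions.
#
# Energies in kBT (beta = 1), lengths in nm. Tensions are reported as
# positive magnitudes opposing channel opening.

new_entropic_tensions <- function(surface, line, model) {
  structure(list(surface_tension = surface, line_tension = line,
                 model = model),
            class = "entropic_tensions")
}

#' @export
print.entropic_tensions <- function(x, ...) {
  cat(sprintf("Entropic tensions (%s)\n", x$model))
  cat(sprintf("  surface tension: %.6g kBT/nm^2\n", x$surface_tension))
  cat(sprintf("  line tension:    %.6g kBT/nm\n", x$line_tension))
  invisible(x)
}

#' Membrane patch for single-crowder entropy calculations
#'
#' A square hard-wall membrane patch of side `side_length` with an entropy
#' discretization length `b` (the lattice constant of the underlying lattice
#' model of translational entropy; it cancels in all entropy differences).
#'
#' @param side_length Box side L in nm.
#' @param discretization_length Lattice constant b in nm (> 0).
#' @return An object of class `box_geometry`.
#' @export
box_geometry <- function(side_length, discretization_length = 1) {
  if (side_length <= 0 || discretization_length <= 0) {
    stop("box dimensions must be positive", call. = FALSE)
  }
  structure(list(side_length = side_length,
                 discretization_length = discretization_length),
            class = "box_geometry")
}

#' Translational entropy of a single crowder around a channel
#'
#' The entropy (in units of kB) of one disk-shaped crowder of radius r in a
#' hard-wall square patch of side L containing a channel of radius R at its
#' center is the log of the area available to the crowder's center of mass:
#' an edge band of width r and an exclusion disk of radius R + r are removed,
#' giving S = ln\[((L - 2r)^2 - pi (R + r)^2) / b^2\].
#'
#' @param box A [box_geometry()].
#' @param channel_radius Channel in-plane radius R in nm (>= 0).
#' @param crowder_radius Crowder radius r in nm (>= 0).
#' @return Entropy in units of kB. Differences between two channel states
#'   are independent of the discretization length b.
#' @examples
#' ig_single_crowder_entropy(box_geometry(10), 0, 0) # log(100)
#' @export
ig_single_crowder_entropy <- function(box, channel_radius, crowder_radius) {
  stopifnot(inherits(box, "box_geometry"))
  if (channel_radius < 0 || crowder_radius < 0) {
    stop("radii must be >= 0", call. = FALSE)
  }
  L <- box$side_length
  r <- crowder_radius
  free_area <- (L - 2 * r)^2 - pi * (channel_radius + r)^2
  if (free_area <= 0) {
    stop("non-positive free area: box too small for this channel/crowder",
         call. = FALSE)
  }
  log(free_area / box$discretization_length^2)
}

#' Ideal-gas entropic tensions of a crowder mixture
#'
#' In the dilute (non-interacting) limit the crowders exert a surface tension
#' equal to the 2D ideal-gas pressure, sigma_c = c, and a line tension
#' tau_c = c <r> arising from the exclusion annulus around the channel. The
#' line tension vanishes as the crowder size goes to zero.
#'
#' @param mixture A [crowder_mixture()].
#' @return An `entropic_tensions` object with `model = "ideal_gas"`;
#'   `surface_tension` in kBT/nm^2, `line_tension` in kBT/nm.
#' @export
ig_tensions <- function(mixture) {
  mom <- mixture_moments(mixture)
  c0 <- mixture$concentration
  new_entropic_tensions(surface = c0, line = c0 * mom$mean_r,
                        model = "ideal_gas")
}

#' Scaled-particle-theory surface tension
#'
#' The entropic surface tension of a hard-disk mixture,
#' sigma_c = c \[ 1/(1 - phi) + phi / ((1 + delta^2)(1 - phi)^2) \],
#' in kBT/nm^2. For uniform crowders (delta^2 = 0) this reduces to
#' c / (1 - phi)^2, a factor 1/(1 - phi)^2 above the ideal-gas law; size
#' variability (delta^2 > 0) reduces the tension at fixed c and phi.
#'
#' @param mixture A [crowder_mixture()].
#' @return sigma_c in kBT/nm^2.
#' @export
spt_surface_tension <- function(mixture) {
  mom <- mixture_moments(mixture)
  phi <- mixture$area_fraction
  c0 <- mixture$concentration
  c0 * (1 / (1 - phi) + phi / ((1 + mom$delta2) * (1 - phi)^2))
}

#' Scaled-particle-theory line tension
#'
#' tau_c = c <r> / (1 - phi), in kBT/nm: the ideal-gas exclusion-annulus
#' term enhanced by the free-area fraction.
#'
#' @param mixture A [crowder_mixture()].
#' @return tau_c in kBT/nm.
#' @export
spt_line_tension <- function(mixture) {
  mom <- mixture_moments(mixture)
  mixture$concentration * mom$mean_r / (1 - mixture$area_fraction)
}

#' Scaled-particle-theory entropic tensions
#'
#' Convenience wrapper bundling [spt_surface_tension()] and
#' [spt_line_tension()].
#'
#' @param mixture A [crowder_mixture()].
#' @return An `entropic_tensions` object with `model = "spt"`.
#' @export
spt_tensions <- function(mixture) {
  new_entropic_tensions(surface = spt_surface_tension(mixture),
                        line = spt_line_tension(mixture),
                        model = "spt")
}

#' Crowding tensions for a named model
#'
#' @param mixture A [crowder_mixture()].
#' @param model `"ideal_gas"` or `"spt"`.
#' @return An `entropic_tensions` object.
#' @export
crowding_tensions <- function(mixture, model = c("spt", "ideal_gas")) {
  model <- match.arg(model)
  switch(model, ideal_gas = ig_tensions(mixture), spt = spt_tensions(mixture))
}

# mu_ex from raw moments; used where state-dependent (c, phi) are needed.
spt_mu_ex_raw <- function(test_radius, c0, mean_r, phi, delta2) {
  if (phi >= 1) stop("area fraction >= 1", call. = FALSE)
  sigma <- c0 * (1 / (1 - phi) + phi / ((1 + delta2) * (1 - phi)^2))
  -log(1 - phi) + 2 * pi * c0 * mean_r * test_radius / (1 - phi) +
    pi * test_radius^2 * sigma
}

#' Excess chemical potential of a test disk (scaled-particle theory)
#'
#' The reversible work, beyond the ideal-gas term, of inserting a hard test
#' disk of radius R into the crowder fluid:
#' mu_ex(R) = -ln(1 - phi) + 2 pi c <r> R / (1 - phi) + pi R^2 sigma_spt,
#' with sigma_spt the SPT surface tension. exp(-mu_ex) is the probability
#' that a randomly placed test disk avoids all overlaps (Widom insertion);
#' at R = 0 this is exactly the free-area fraction 1 - phi.
#'
#' @param test_radius Test-disk radius R in nm (>= 0).
#' @param mixture A [crowder_mixture()].
#' @return mu_ex in kBT.
#' @export
spt_excess_chemical_potential <- function(test_radius, mixture) {
  if (any(test_radius < 0)) stop("`test_radius` must be >= 0", call. = FALSE)
  mom <- mixture_moments(mixture)
  spt_mu_ex_raw(test_radius, mixture$concentration, mom$mean_r,
                mixture$area_fraction, mom$delta2)
}

#' Free-energy change of a membrane area change at fixed crowder numbers
#'
#' Integrates the scaled-particle surface tension over an area change at
#' fixed copy numbers. With N total disks, occupied area B = pi sum(n_i r_i^2)
#' and C = pi (sum(n_i r_i))^2, the closed form is
#' dF = -\[ N ln((A2 - B)/(A1 - B)) - C (1/(A2 - B) - 1/(A1 - B)) \],
#' under the sign convention dF = -sigma dA (the crowders' free energy falls
#' as the membrane grows). Its derivative with respect to A2 reproduces
#' -sigma of the equation of state at that state.
#'
#' @param area_from Initial total area A1 in nm^2.
#' @param area_to Final total area A2 in nm^2.
#' @param radii Disk radii per species (nm).
#' @param copy_numbers Disk copy numbers per species (may be non-integer when
#'   representing an average composition).
#' @return Free-energy change in kBT.
#' @export
spt_area_change_free_energy <- function(area_from, area_to, radii,
                                        copy_numbers) {
  if (length(radii) != length(copy_numbers)) {
    stop("`radii` and `copy_numbers` must have equal length", call. = FALSE)
  }
  if (any(radii < 0) || any(copy_numbers < 0)) {
    stop("radii and copy numbers must be >= 0", call. = FALSE)
  }
  N <- sum(copy_numbers)
  B <- pi * sum(copy_numbers * radii^2)
  C <- pi * sum(copy_numbers * radii)^2
  if (area_from <= B || area_to <= B) {
    stop("total area must exceed the occupied disk area (over-packed)",
         call. = FALSE)
  }
  -(N * log((area_to - B) / (area_from - B)) -
      C * (1 / (area_to - B) - 1 / (area_from - B)))
}
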