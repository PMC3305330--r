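# Gating energetics: geometry + entropic tensions -> free-energy changes,
# gating-tension shifts, and two-state open-probability curves.
#
# Ensembles:
#   * constant area   — the whole membrane patch has fixed area; opening
#     removes free area, so both the surface- and line-tension terms act:
#     dG_crowd = sigma_c dA + tau_c dC.
#   * constant tension — a loading device holds the tension fixed and the
#     total area adjusts so the lipid area is conserved; the surface-tension
#     term cancels and only the exclusion-annulus (line-tension) term
#     survives: dG_crowd = tau_c dC, plus loading work -sigma dA.

#' Channel gating geometry
#'
#' In-plane radii of the closed and open conformations of a disk-shaped
#' channel. For an opening transition `open_radius > closed_radius`; a
#' closing transition is allowed and simply flips the signs of the derived
#' area and circumference changes.
#'
#' @param closed_radius Closed-state radius R_c in nm (> 0).
#' @param open_radius Open-state radius R_o in nm (> 0).
#' @return An object of class `channel_geometry`.
#' @examples
#' mscl <- channel_geometry(2.4, 3.5)
#' geometry_deltas(mscl)
#' @export
channel_geometry <- function(closed_radius, open_radius) {
  if (closed_radius <= 0 || open_radius <= 0) {
    stop("channel radii must be > 0", call. = FALSE)
  }
  structure(list(closed_radius = closed_radius, open_radius = open_radius),
            class = "channel_geometry")
}

#' Area and circumference change upon gating
#'
#' @param channel A [channel_geometry()].
#' @return A list with `delta_area` = pi (R_o^2 - R_c^2) in nm^2 and
#'   `delta_circumference` = 2 pi (R_o - R_c) in nm.
#' @export
geometry_deltas <- function(channel) {
  stopifnot(inherits(channel, "channel_geometry"))
  list(
    delta_area = pi * (channel$open_radius^2 - channel$closed_radius^2),
    delta_circumference = 2 * pi * (channel$open_radius - channel$closed_radius)
  )
}

new_gating_result <- function(crowding, loading, ensemble, model, delta_area) {
  structure(list(crowding_energy = crowding,
                 loading_energy = loading,
                 total = crowding + loading,
                 gating_tension_shift = if (delta_area != 0) crowding / delta_area else NA_real_,
                 ensemble = ensemble, model = model,
                 delta_area = delta_area),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("Gating free-energy change (%s ensemble, %s model)\n",
              x$ensemble, x$model))
  cat(sprintf("  crowding:             %8.3f kBT\n", x$crowding_energy))
  cat(sprintf("  loading device:       %8.3f kBT\n", x$loading_energy))
  cat(sprintf("  total:                %8.3f kBT\n", x$total))
  cat(sprintf("  gating-tension shift: %8.4f kBT/nm^2\n",
              x$gating_tension_shift))
  invisible(x)
}

#' Crowding contribution to gating at constant membrane area
#'
#' dG_crowd = sigma_c dA + tau_c dC, with the tensions from the chosen
#' model. There is no loading device in this ensemble.
#'
#' @param channel A [channel_geometry()].
#' @param mixture A [crowder_mixture()].
#' @param model `"spt"` (default) or `"ideal_gas"`.
#' @return A `gating_result` with `ensemble = "constant_area"`.
#' @examples
#' mscl <- channel_geometry(2.4, 3.5)
#' crowders <- uniform_mixture(1, area_fraction = 0.5)
#' gating_energy_constant_area(mscl, crowders, model = "ideal_gas") # 4.3 kBT
#' gating_energy_constant_area(mscl, crowders, model = "spt")       # 15.2 kBT
#' @export
gating_energy_constant_area <- function(channel, mixture,
                                        model = c("spt", "ideal_gas")) {
  model <- match.arg(model)
  tens <- crowding_tensions(mixture, model)
  d <- geometry_deltas(channel)
  crowding <- tens$surface_tension * d$delta_area +
    tens$line_tension * d$delta_circumference
  new_gating_result(crowding, loading = 0, ensemble = "constant_area",
                    model = model, delta_area = d$delta_area)
}

#' Crowding contribution to gating at constant applied tension
#'
#' With the tension held by a loading device the lipid area is conserved
#' and the crowders' surface-tension term cancels: only the exclusion-
#' annulus term survives, dG_crowd = tau_c dC. The loading device relaxes
#' by -sigma dA as the channel opens.
#'
#' @param channel A [channel_geometry()].
#' @param mixture A [crowder_mixture()].
#' @param applied_tension Applied membrane tension sigma in kBT/nm^2.
#' @param model `"spt"` (default) or `"ideal_gas"`; only the line tension
#'   differs between the two in this ensemble.
#' @return A `gating_result` with `ensemble = "constant_tension"`;
#'   `total = tau_c dC - sigma dA`.
#' @examples
#' mscl <- channel_geometry(2.4, 3.5)
#' crowders <- uniform_mixture(1, area_fraction = 0.5)
#' gating_energy_constant_tension(mscl, crowders, model = "spt") # 2.2 kBT
#' @export
gating_energy_constant_tension <- function(channel, mixture,
                                           applied_tension = 0,
                                           model = c("spt", "ideal_gas")) {
  model <- match.arg(model)
  tens <- crowding_tensions(mixture, model)
  d <- geometry_deltas(channel)
  crowding <- tens$line_tension * d$delta_circumference
  loading <- -applied_tension * d$delta_area
  new_gating_result(crowding, loading, ensemble = "constant_tension",
                    model = model, delta_area = d$delta_area)
}

#' Crowding-induced shift of the gating tension
#'
#' The increase in the tension at which the channel gates, measurable in
#' patch-clamp experiments: the crowding energy divided by the gating area
#' change, dG_crowd / dA.
#'
#' @param gating_result A `gating_result` from
#'   [gating_energy_constant_area()] or [gating_energy_constant_tension()].
#' @return Gating-tension shift in kBT/nm^2. Errors if dA = 0.
#' @export
gating_tension_shift <- function(gating_result) {
  stopifnot(inherits(gating_result, "gating_result"))
  if (gating_result$delta_area == 0) {
    stop("gating-tension shift undefined for zero area change", call. = FALSE)
  }
  gating_result$crowding_energy / gating_result$delta_area
}

#' Two-state open probability versus applied tension
#'
#' For a two-state channel in the constant-tension ensemble, all
#' non-crowding contributions to the gating free energy are lumped into the
#' bare gating tension sigma*_0, so that
#' dG(sigma) = (sigma*_0 - sigma) dA + tau_c dC and
#' P_open = 1 / (1 + exp(dG)) (energies in kBT). Crowding shifts the
#' midpoint (P_open = 1/2) from sigma*_0 to sigma*_0 + tau_c dC / dA.
#'
#' @param applied_tension Applied tension sigma in kBT/nm^2 (vectorized).
#' @param gating_tension Bare gating tension sigma*_0 in kBT/nm^2.
#' @param channel A [channel_geometry()].
#' @param mixture A [crowder_mixture()], or `NULL` for an uncrowded channel.
#' @param model `"spt"` (default) or `"ideal_gas"`; ignored when
#'   `mixture` is `NULL`.
#' @return P_open in `[0, 1]`, same length as `applied_tension`.
#' @export
open_probability <- function(applied_tension, gating_tension, channel,
                             mixture = NULL, model = c("spt", "ideal_gas")) {
  model <- match.arg(model)
  d <- geometry_deltas(channel)
  tau <- if (is.null(mixture)) 0 else crowding_tensions(mixture, model)$line_tension
  dG <- (gating_tension - applied_tension) * d$delta_area +
    tau * d$delta_circumference
  1 / (1 + exp(dG))
}

#' Consistency of the three-step constant-tension route
#'
#' Cross-checks the closed-form constant-tension gating energy
#' (tau_c dC - sigma dA) against an explicit three-step thermodynamic route
#' evaluated at finite membrane area A0: (i) removal of the closed channel
#' at total area A0 + pi R_c^2, (ii) a crowders-only total-area change that
#' conserves the lipid area, including the loading-device work, and (iii)
#' insertion of the open channel at total area A0 + pi R_o^2. Each step uses
#' the full scaled-particle expressions at the state-specific density and
#' packing fraction (plus the single-channel ideal translational term). The
#' difference between the two routes is a finite-size residual of order
#' 1/A0, vanishing in the thermodynamic limit.
#'
#' @param channel A [channel_geometry()].
#' @param mixture A [crowder_mixture()]; its density and area fraction are
#'   interpreted at the channel-free reference area `reference_area`.
#' @param applied_tension Applied tension sigma in kBT/nm^2.
#' @param reference_area Channel-free membrane area A0 in nm^2 over which
#'   the mixture's concentration applies.
#' @return The residual (three-step minus closed form) in kBT.
#' @export
constant_tension_decomposition_check <- function(channel, mixture,
                                                 applied_tension = 0,
                                                 reference_area = 1e6) {
  stopifnot(inherits(channel, "channel_geometry"),
            inherits(mixture, "crowder_mixture"))
  A0 <- reference_area
  mom <- mixture_moments(mixture)
  d <- geometry_deltas(channel)

  # crowder composition at the reference area
  n_tot <- mixture$concentration * A0
  counts <- n_tot * mixture$weights
  B <- pi * sum(counts * mixture$radii^2)       # occupied crowder area
  sum_r <- sum(counts * mixture$radii)

  A_closed <- A0 + pi * channel$closed_radius^2
  A_open <- A0 + pi * channel$open_radius^2
  if (min(A_closed, A_open) <= B) {
    stop("reference area too small for the crowder load", call. = FALSE)
  }

  state_mu <- function(R, A) {
    if (n_tot == 0) return(0)
    c_loc <- n_tot / A
    phi_loc <- B / A
    mr_loc <- sum_r / n_tot
    # delta2 of the actual composition (override honored as in the mixture)
    mr2_loc <- sum(counts * mixture$radii^2) / n_tot
    d2_loc <- max(0, (mr2_loc - mr_loc^2) / mr_loc^2)
    if (!is.null(mixture$delta2_override)) d2_loc <- mixture$delta2_override
    spt_mu_ex_raw(R, c_loc, mr_loc, phi_loc, d2_loc)
  }

  # three-step route: remove closed channel, grow area, insert open channel.
  # The channel's own ideal translational term is O(dA/A0) and belongs to
  # the small terms the expansion discards; only excess parts enter here.
  removal <- -state_mu(channel$closed_radius, A_closed)
  area_step <- spt_area_change_free_energy(A_closed, A_open,
                                           mixture$radii, counts)
  insertion <- state_mu(channel$open_radius, A_open)
  loading <- -applied_tension * (A_open - A_closed)
  three_step <- removal + area_step + insertion + loading

  closed_form <- spt_line_tension(mixture) * d$delta_circumference -
    applied_tension * d$delta_area

  three_step - closed_form
}
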