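# Hard-disk Monte Carlo oracle.
#
# Independent numerical check of the scaled-particle predictions: Metropolis
# sampling of hard disks in a periodic square box (minimum-image convention)
# with Widom test-particle insertion to estimate the excess chemical
# potential, exp(-mu_ex) = P(random test disk avoids all overlaps).
# Periodic boundaries remove the wall effects that the analytic expansions
# neglect; the hard-wall single-crowder geometry is handled separately by
# exact_free_area_one_crowder().

#' Monte Carlo run settings
#'
#' @param n_sweeps Number of sampling sweeps after equilibration (one sweep
#'   = one attempted move per disk).
#' @param n_equilibration Equilibration sweeps, during which the step size is
#'   tuned towards ~40% acceptance and then frozen.
#' @param max_step Initial maximum displacement per move in nm; `NULL` picks
#'   half the mean disk radius (or 0.1 nm for point particles).
#' @param seed Integer seed for the run.
#' @param n_insertions_per_sample Widom trial insertions per stored sample.
#' @param sample_interval Sweeps between stored samples (decorrelation gap).
#' @return A list of class `mc_settings`.
#' @export
mc_settings <- function(n_sweeps = 1000, n_equilibration = 300,
                        max_step = NULL, seed = 1,
                        n_insertions_per_sample = 2000,
                        sample_interval = 20) {
  stopifnot(n_sweeps >= 1, n_equilibration >= 0,
            n_insertions_per_sample >= 1, sample_interval >= 1)
  structure(list(n_sweeps = as.integer(n_sweeps),
                 n_equilibration = as.integer(n_equilibration),
                 max_step = max_step,
                 seed = as.integer(seed),
                 n_insertions_per_sample = as.integer(n_insertions_per_sample),
                 sample_interval = as.integer(sample_interval)),
            class = "mc_settings")
}

# squared minimum-image separation of point (x, y) from all rows of centers
.min_image_d2 <- function(x, y, centers, box) {
  dx <- centers[, 1] - x
  dy <- centers[, 2] - y
  dx <- dx - box * round(dx / box)
  dy <- dy - box * round(dy / box)
  dx * dx + dy * dy
}

.any_overlap <- function(config) {
  n <- nrow(config$centers)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    d2 <- .min_image_d2(config$centers[i, 1], config$centers[i, 2],
                        config$centers[(i + 1):n, , drop = FALSE],
                        config$box_side)
    if (any(d2 < (config$radii[i] + config$radii[(i + 1):n])^2 - 1e-12)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Periodic hard-disk configuration
#'
#' @param box_side Side length of the periodic square box (nm).
#' @param centers N x 2 matrix of disk centers, each coordinate in
#'   `[0, box_side)`.
#' @param radii Length-N vector of disk radii (nm, >= 0).
#' @param check Verify the no-overlap invariant under the minimum-image
#'   metric (default `TRUE`).
#' @return An object of class `disk_configuration`.
#' @export
disk_configuration <- function(box_side, centers, radii, check = TRUE) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  radii <- as.numeric(radii)
  stopifnot(box_side > 0, nrow(centers) == length(radii), all(radii >= 0))
  if (any(centers < 0) || any(centers >= box_side)) {
    stop("all centers must lie in [0, box_side)^2", call. = FALSE)
  }
  cfg <- structure(list(box_side = box_side, centers = centers, radii = radii),
                   class = "disk_configuration")
  if (check && .any_overlap(cfg)) {
    stop("overlapping disks in configuration", call. = FALSE)
  }
  cfg
}

#' Random non-overlapping starting configuration
#'
#' Random sequential insertion of `target_n` disks whose species are drawn
#' from the mixture's abundances. Feasible only well below close packing;
#' the requested packing fraction must stay below 0.7.
#'
#' @param box_side Periodic box side (nm).
#' @param mixture A [crowder_mixture()] supplying radii and abundances (its
#'   concentration is ignored; density is set by `target_n` and the box).
#' @param target_n Number of disks to place.
#' @param seed Integer seed; the same seed reproduces the configuration.
#' @param max_attempts Total insertion attempts before giving up.
#' @return A `disk_configuration`.
#' @export
init_configuration <- function(box_side, mixture, target_n, seed,
                               max_attempts = 1000L * target_n) {
  stopifnot(inherits(mixture, "crowder_mixture"), target_n >= 1)
  set.seed(seed)
  species <- sample.int(length(mixture$radii), target_n, replace = TRUE,
                        prob = mixture$weights)
  radii <- mixture$radii[species]
  phi_req <- pi * sum(radii^2) / box_side^2
  if (phi_req >= 0.7) {
    stop(sprintf(
      "requested packing fraction %.2f too high for random sequential insertion (< 0.7); lower the density or enlarge the box",
      phi_req), call. = FALSE)
  }
  if (box_side <= 2 * max(radii)) {
    stop("box side must exceed the largest disk diameter", call. = FALSE)
  }
  centers <- matrix(NA_real_, nrow = target_n, ncol = 2)
  placed <- 0L
  attempts <- 0L
  while (placed < target_n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("random sequential insertion failed; lower the packing fraction",
           call. = FALSE)
    }
    x <- stats::runif(1, 0, box_side)
    y <- stats::runif(1, 0, box_side)
    ok <- placed == 0L ||
      all(.min_image_d2(x, y, centers[seq_len(placed), , drop = FALSE],
                        box_side) >=
            (radii[placed + 1L] + radii[seq_len(placed)])^2)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- c(x, y)
    }
  }
  disk_configuration(box_side, centers, radii, check = FALSE)
}

#' Metropolis sampling of a hard-disk fluid
#'
#' Single-disk uniform displacement moves under periodic boundaries; any
#' move creating an overlap is rejected (detailed balance for the hard-disk
#' Boltzmann measure). The step size is tuned towards ~40% acceptance during
#' equilibration and then frozen. Decorrelated configurations are stored
#' every `sample_interval` sweeps.
#'
#' @param config A starting [disk_configuration()].
#' @param settings An [mc_settings()].
#' @return A list of class `mc_run` with `samples` (list of
#'   `disk_configuration`), `acceptance_rate` (sampling phase), `step`
#'   (frozen step size, nm), and `settings`.
#' @export
run_metropolis <- function(config, settings = mc_settings()) {
  stopifnot(inherits(config, "disk_configuration"),
            inherits(settings, "mc_settings"))
  set.seed(settings$seed)
  L <- config$box_side
  centers <- config$centers
  radii <- config$radii
  n <- nrow(centers)
  step <- settings$max_step
  if (is.null(step)) step <- max(0.1, 0.5 * mean(radii))
  pair_r <- outer(radii, radii, "+")^2

  do_sweep <- function(step) {
    acc <- 0L
    order_idx <- sample.int(n)
    disp <- matrix(stats::runif(2 * n, -step, step), ncol = 2)
    for (k in seq_len(n)) {
      i <- order_idx[k]
      x <- (centers[i, 1] + disp[k, 1]) %% L
      y <- (centers[i, 2] + disp[k, 2]) %% L
      d2 <- .min_image_d2(x, y, centers, L)
      d2[i] <- Inf
      if (all(d2 >= pair_r[i, ])) {
        centers[i, ] <<- c(x, y)
        acc <- acc + 1L
      }
    }
    acc
  }

  # equilibrate, tuning the step toward ~40% acceptance
  tune_block <- 25L
  accepted <- 0L
  for (s in seq_len(settings$n_equilibration)) {
    accepted <- accepted + do_sweep(step)
    if (s %% tune_block == 0L) {
      rate <- accepted / (tune_block * n)
      if (rate > 0.45) step <- min(step * 1.25, L / 4)
      if (rate < 0.35) step <- step * 0.8
      accepted <- 0L
    }
  }

  samples <- vector("list", settings$n_sweeps %/% settings$sample_interval)
  n_samp <- 0L
  accepted <- 0L
  for (s in seq_len(settings$n_sweeps)) {
    accepted <- accepted + do_sweep(step)
    if (s %% settings$sample_interval == 0L) {
      n_samp <- n_samp + 1L
      samples[[n_samp]] <- disk_configuration(L, centers, radii, check = FALSE)
    }
  }
  structure(list(samples = samples[seq_len(n_samp)],
                 acceptance_rate = accepted / (settings$n_sweeps * n),
                 step = step,
                 settings = settings),
            class = "mc_run")
}

#' Widom test-particle insertion probability
#'
#' Estimates the probability that a hard test disk of radius R, placed
#' uniformly at random in the periodic box, overlaps none of the fluid
#' disks. This equals exp(-mu_ex(R)); the standard error is computed from
#' the between-sample spread.
#'
#' @param samples A list of [disk_configuration()]s (e.g. `mc_run$samples`),
#'   or an `mc_run`.
#' @param test_radius Test-disk radius R in nm (>= 0). `R + max(radii)` must
#'   stay below half the box side for the minimum-image convention to hold.
#' @param n_insertions Trial insertions per sample.
#' @param seed Integer seed for the insertion points.
#' @return A list with `p_hat`, `stderr`, `mu_ex` (= -log(p_hat)), and
#'   `n_samples`.
#' @export
widom_insertion_probability <- function(samples, test_radius,
                                        n_insertions = 2000, seed = 1) {
  if (inherits(samples, "mc_run")) samples <- samples$samples
  stopifnot(length(samples) >= 1, test_radius >= 0, n_insertions >= 1)
  L <- samples[[1]]$box_side
  rmax <- if (length(samples[[1]]$radii)) max(samples[[1]]$radii) else 0
  if (test_radius + rmax >= L / 2) {
    stop("test radius too large for the box: minimum-image convention violated",
         call. = FALSE)
  }
  set.seed(seed)
  p_s <- vapply(samples, function(cfg) {
    n <- nrow(cfg$centers)
    if (n == 0L) return(1)
    pts <- matrix(stats::runif(2 * n_insertions, 0, L), ncol = 2)
    contact2 <- (test_radius + cfg$radii)^2
    ok <- vapply(seq_len(n_insertions), function(j) {
      all(.min_image_d2(pts[j, 1], pts[j, 2], cfg$centers, L) >= contact2)
    }, logical(1))
    mean(ok)
  }, numeric(1))
  p_hat <- mean(p_s)
  se <- if (length(p_s) > 1) stats::sd(p_s) / sqrt(length(p_s)) else NA_real_
  list(p_hat = p_hat, stderr = se, mu_ex = -log(p_hat),
       n_samples = length(p_s))
}

#' Exact free area for one crowder around a centered channel (hard walls)
#'
#' Closed form for the area available to the center of mass of a single
#' crowder of radius r in a hard-wall square patch of side L with a channel
#' of radius R at the center: the edge band of width r and the exclusion
#' disk of radius R + r are removed, giving (L - 2r)^2 - pi (R + r)^2. The
#' exclusion disk must fit entirely inside the allowed band.
#'
#' @param box_side Patch side L (nm).
#' @param channel_radius Channel radius R (nm, >= 0).
#' @param crowder_radius Crowder radius r (nm, >= 0).
#' @return Free area in nm^2.
#' @seealso [grid_free_area()] for a brute-force cross-check.
#' @export
exact_free_area_one_crowder <- function(box_side, channel_radius,
                                        crowder_radius) {
  L <- box_side; R <- channel_radius; r <- crowder_radius
  stopifnot(L > 0, R >= 0, r >= 0)
  if (L - 2 * r <= 0 || R + r > L / 2 - r) {
    stop("exclusion disk does not fit inside the allowed band", call. = FALSE)
  }
  area <- (L - 2 * r)^2 - pi * (R + r)^2
  if (area <= 0) stop("non-positive free area", call. = FALSE)
  area
}

#' Grid-integration estimate of the single-crowder free area
#'
#' Riemann-sum counterpart of [exact_free_area_one_crowder()]: counts grid
#' points of an n x n lattice over the patch that lie outside both the edge
#' band and the exclusion disk. Converges to the closed form as n grows.
#'
#' @inheritParams exact_free_area_one_crowder
#' @param n_grid Grid points per side.
#' @return Estimated free area in nm^2.
#' @export
grid_free_area <- function(box_side, channel_radius, crowder_radius,
                           n_grid = 2000) {
  L <- box_side; R <- channel_radius; r <- crowder_radius
  u <- (seq_len(n_grid) - 0.5) * L / n_grid
  inside_band <- u >= r & u <= L - r
  d2x <- (u - L / 2)^2
  # fraction of grid cells allowed: band in both coords, outside exclusion disk
  count <- 0
  thr2 <- (R + r)^2
  for (ix in which(inside_band)) {
    ok <- inside_band & (d2x[ix] + d2x) > thr2
    count <- count + sum(ok)
  }
  count * (L / n_grid)^2
}

#' Validate scaled-particle theory against Widom insertion
#'
#' For each requested area fraction, equilibrates a hard-disk fluid drawn
#' from the mixture composition in a periodic box and compares the Widom
#' estimate of the excess chemical potential with the scaled-particle
#' prediction, at a set of test-disk radii expressed in units of the mean
#' crowder radius.
#'
#' @param phi_values Area fractions to probe.
#' @param mixture_radii Crowder radii (nm); default a single 1 nm species.
#' @param abundances Relative abundances for `mixture_radii`.
#' @param test_radius_factors Test radii as multiples of the mean crowder
#'   radius.
#' @param box_factor Box side in units of the mean crowder radius.
#' @param settings An [mc_settings()]; its seed controls the whole sweep.
#' @return A data.frame with columns `phi` (realized area fraction), `R`
#'   (test radius, nm), `mu_spt`, `mu_mc`, `p_hat`, `stderr`, and `n_disks`.
#' @export
mc_validate_spt <- function(phi_values = c(0.1, 0.2, 0.3),
                            mixture_radii = 1, abundances = NULL,
                            test_radius_factors = c(0, 0.5, 1),
                            box_factor = 40,
                            settings = mc_settings()) {
  if (is.null(abundances)) abundances <- rep(1, length(mixture_radii))
  proto <- crowder_mixture(mixture_radii, abundances, concentration = 0)
  mom <- mixture_moments(proto)
  L <- box_factor * mom$mean_r
  out <- list()
  for (k in seq_along(phi_values)) {
    phi <- phi_values[k]
    n <- max(2L, round(phi * L^2 / (pi * mom$mean_r2)))
    cfg <- init_configuration(L, proto, n, seed = settings$seed + k)
    run <- run_metropolis(cfg, mc_settings(
      n_sweeps = settings$n_sweeps,
      n_equilibration = settings$n_equilibration,
      max_step = settings$max_step,
      seed = settings$seed + 1000L + k,
      n_insertions_per_sample = settings$n_insertions_per_sample,
      sample_interval = settings$sample_interval))
    # realized state of the finite sample
    phi_real <- pi * sum(cfg$radii^2) / L^2
    state <- crowder_mixture(cfg$radii, rep(1, length(cfg$radii)),
                             concentration = n / L^2)
    for (f in test_radius_factors) {
      R <- f * mom$mean_r
      w <- widom_insertion_probability(
        run, R, n_insertions = settings$n_insertions_per_sample,
        seed = settings$seed + 2000L + 10L * k + round(100 * f))
      out[[length(out) + 1L]] <- data.frame(
        phi = phi_real, R = R,
        mu_spt = spt_excess_chemical_potential(R, state),
        mu_mc = w$mu_ex, p_hat = w$p_hat, stderr = w$stderr, n_disks = n)
    }
  }
  do.call(rbind, out)
}
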