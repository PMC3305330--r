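# Transmembrane-helix census -> disk radii.
#
# Proteomic surveys report membrane-protein abundance binned by the number of
# predicted transmembrane (TM) helices. Modelling each protein as a disk
# whose in-plane area is (helix count) x (per-helix footprint) gives
# r = sqrt(n * a_helix / pi), i.e. r proportional to sqrt(n).

#' Transmembrane-helix abundance table
#'
#' @param n_helices Positive integer vector of TM-helix counts per protein
#'   class. Proteins with zero predicted TM helices are excluded from the
#'   disk model and are rejected here.
#' @param abundance Relative abundances (unitless weights, >= 0, not all
#'   zero).
#' @return An object of class `tm_helix_table`: a data.frame with columns
#'   `n_helices` and `abundance`.
#' @export
tm_helix_table <- function(n_helices, abundance) {
  n_helices <- as.numeric(n_helices)
  abundance <- as.numeric(abundance)
  if (length(n_helices) == 0L) stop("empty TM-helix table", call. = FALSE)
  if (length(abundance) != length(n_helices)) {
    stop("`n_helices` and `abundance` must have equal length", call. = FALSE)
  }
  if (anyNA(n_helices) || any(n_helices < 1) ||
      any(n_helices != round(n_helices))) {
    stop("`n_helices` must be positive integers (zero-TM proteins are excluded)",
         call. = FALSE)
  }
  if (anyNA(abundance) || any(abundance < 0) || sum(abundance) == 0) {
    stop("`abundance` must be nonnegative weights with at least one > 0",
         call. = FALSE)
  }
  structure(data.frame(n_helices = as.integer(n_helices),
                       abundance = abundance),
            class = c("tm_helix_table", "data.frame"))
}

#' Read a TM-helix abundance table from TSV
#'
#' Expects a headered tab-separated file with columns `n_tm_helices`
#' (positive integer) and `abundance` (nonnegative float). Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A [tm_helix_table()].
#' @export
read_tm_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  required <- c("n_tm_helices", "abundance")
  if (!all(required %in% names(df))) {
    stop(sprintf("TM table must have columns %s; found: %s",
                 paste(required, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  tm_helix_table(df$n_tm_helices, df$abundance)
}

#' Disk radius of a protein with a given number of TM helices
#'
#' Models the protein as a disk whose in-plane area equals the helix count
#' times a per-helix footprint: r = sqrt(n * footprint / pi). The default
#' footprint of 1.4 nm^2 per helix reflects typical structural estimates and
#' is configurable.
#'
#' @param n_helices Number of transmembrane helices (integer >= 1).
#' @param helix_footprint In-plane area per helix, nm^2 (> 0).
#' @return Disk radius in nm.
#' @examples
#' radius_from_tm_helices(4, helix_footprint = pi) # exactly 2 nm
#' @export
radius_from_tm_helices <- function(n_helices, helix_footprint = 1.4) {
  if (any(n_helices < 1)) {
    stop("`n_helices` must be >= 1 (zero-TM proteins are excluded)",
         call. = FALSE)
  }
  if (any(helix_footprint <= 0)) {
    stop("`helix_footprint` must be > 0", call. = FALSE)
  }
  sqrt(n_helices * helix_footprint / pi)
}

#' Relative radius variance implied by a TM-helix distribution
#'
#' With r proportional to sqrt(n), the relative radius variance of the
#' implied disk mixture is delta^2 = <n> / <sqrt(n)>^2 - 1 (abundance-
#' weighted averages). The per-helix footprint cancels, so the result is
#' independent of it.
#'
#' @param table A [tm_helix_table()].
#' @return delta^2 (unitless, >= 0).
#' @examples
#' tab <- tm_helix_table(c(1, 4), c(1, 1))
#' delta2_from_tm_distribution(tab) # 2.5 / 1.5^2 - 1 = 1/9
#' @export
delta2_from_tm_distribution <- function(table) {
  stopifnot(inherits(table, "tm_helix_table"))
  w <- table$abundance / sum(table$abundance)
  mean_n <- sum(w * table$n_helices)
  mean_sqrt_n <- sum(w * sqrt(table$n_helices))
  max(0, mean_n / mean_sqrt_n^2 - 1)
}

#' Build a crowder mixture from a TM-helix table
#'
#' Converts each helix-count class to a disk radius via
#' [radius_from_tm_helices()] and carries the abundances over as mixture
#' weights.
#'
#' @param table A [tm_helix_table()].
#' @param helix_footprint Per-helix in-plane footprint in nm^2.
#' @inheritParams crowder_mixture
#' @return A [crowder_mixture()].
#' @export
mixture_from_tm_table <- function(table, helix_footprint = 1.4,
                                  concentration = NULL, area_fraction = NULL) {
  stopifnot(inherits(table, "tm_helix_table"))
  crowder_mixture(
    radii = radius_from_tm_helices(table$n_helices, helix_footprint),
    abundances = table$abundance,
    concentration = concentration,
    area_fraction = area_fraction
  )
}
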