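#' Unit system: conversion between molecule counts and micromolar pools
#'
#' All model dynamics in this package run on integer molecule counts; rate
#' constants are quoted in the bulk units used throughout the centrosome
#' literature (uM^-1 s^-1 for bimolecular steps, s^-1 for unimolecular
#' steps). The bridge between the two is the factor `count_per_uM_um3`, the
#' number of molecules contained in 1 um^3 of a 1 uM solution:
#' 10^-6 mol/L x N_A x 10^-15 L/um^3 = 602.214. Every bimolecular propensity
#' is normalized as k / (c * Vc), with c this factor.
#'
#' Two conventions are supported:
#' \describe{
#'   \item{"avogadro"}{c = 602.214 (physical counts). This is the pinned
#'     default: it reproduces the calibrated steady-state sizes (a few um^3)
#'     and places the cooperative/non-cooperative equality boundary where the
#'     deterministic analysis puts it.}
#'   \item{"unity"}{c = 1, i.e. a pool of concentration rho in a cell of
#'     volume Vc holds N = rho * Vc "molecules". This reduced count scale is
#'     used for stochastic ensemble statistics, where the smaller pools give
#'     desk-scale run times and fluctuations of the magnitude discussed in
#'     the robustness analyses.}
#' }
#'
#' @param convention `"avogadro"` or `"unity"`.
#' @return An object of class `unit_system` with fields `count_per_uM_um3`
#'   and `convention_id`.
#' @examples
#' unit_system("avogadro")$count_per_uM_um3 # 602.214
#' @export
unit_system <- function(convention = c("avogadro", "unity")) {
  convention <- match.arg(convention)
  c_factor <- switch(convention, avogadro = 602.214076, unity = 1.0)
  structure(list(count_per_uM_um3 = c_factor, convention_id = convention),
            class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf("<unit_system '%s': %g molecules per uM per um^3>\n",
              x$convention_id, x$count_per_uM_um3))
  invisible(x)
}

as_unit_system <- function(units) {
  if (inherits(units, "unit_system")) return(units)
  if (is.character(units)) return(unit_system(units))
  stop("`units` must be a unit_system object or a convention name")
}

#' Fixed model parameters
#'
#' The parameters held fixed across all growth models: the effective volume
#' of one PCM subunit, the default initial centrosome volume, the subunit
#' disassembly rate constant, and the cell volume.
#'
#' @param delta_v Subunit volume (um^3). Default 2e-4.
#' @param V0 Default initial centrosome volume (um^3). Default 5e-3.
#' @param k_minus Disassembly rate constant (s^-1). Default 5e-3.
#' @param Vc Cell volume (um^3). Default 5000.
#' @return A list of class `fixed_params`.
#' @export
fixed_params <- function(delta_v = 2e-4, V0 = 5e-3, k_minus = 5e-3, Vc = 5000) {
  stopifnot(delta_v > 0, V0 > 0, k_minus > 0, Vc > 0)
  structure(list(delta_v = delta_v, V0 = V0, k_minus = k_minus, Vc = Vc),
            class = "fixed_params")
}

#' Convert a cytoplasmic concentration to a molecule count
#'
#' @param rho Concentration (uM), non-negative.
#' @param Vc Volume (um^3), positive.
#' @param units A [unit_system()] (or convention name).
#' @return Integer molecule count, `round(rho * Vc * c)` (round half to even).
#' @seealso [count_to_concentration()]
#' @export
concentration_to_count <- function(rho, Vc, units = unit_system()) {
  units <- as_unit_system(units)
  if (any(rho < 0)) stop("concentration must be non-negative")
  if (any(Vc <= 0)) stop("volume must be positive")
  round(rho * Vc * units$count_per_uM_um3)
}

#' Convert a molecule count to a cytoplasmic concentration
#'
#' Inverse of [concentration_to_count()] up to rounding.
#'
#' @param n Molecule count, non-negative.
#' @param Vc Volume (um^3), positive.
#' @param units A [unit_system()] (or convention name).
#' @return Concentration in uM.
#' @export
count_to_concentration <- function(n, Vc, units = unit_system()) {
  units <- as_unit_system(units)
  if (any(n < 0)) stop("count must be non-negative")
  if (any(Vc <= 0)) stop("volume must be positive")
  n / (Vc * units$count_per_uM_um3)
}

#' Centrosome volume from subunit count
#'
#' Centrosome volume is the number of incorporated subunits times the
#' effective subunit volume, V = n * delta_v.
#'
#' @param n Subunit count (non-negative; may be fractional for deterministic
#'   states).
#' @param delta_v Subunit volume (um^3).
#' @return Volume in um^3.
#' @export
volume_of <- function(n, delta_v = fixed_params()$delta_v) {
  if (any(n < 0)) stop("subunit count must be non-negative")
  n * delta_v
}

#' Initial subunit counts for a centrosome pair
#'
#' Converts an initial mean volume `V0` and an initial volume difference
#' `dV0` into the pair of starting subunit counts, under one of three
#' assignment protocols:
#' \describe{
#'   \item{symmetric_split}{`(V0 + dV0/2, V0 - dV0/2) / delta_v` - the
#'     difference is split symmetrically about `V0`; requires `dV0 < 2 V0`.}
#'   \item{deficit_on_first}{`(V0 - dV0, V0) / delta_v` - the first
#'     centrosome starts smaller (used in the differential-activity
#'     protocol, where the higher-activity centrosome is handicapped);
#'     requires `dV0 < V0`.}
#'   \item{excess_on_first}{`(V0 + dV0, V0) / delta_v` - the first
#'     centrosome starts larger by the full `dV0`; accommodates protocols
#'     where the imposed difference exceeds the seed volume.}
#' }
#' Counts are rounded half-to-even and clamped to at least one subunit (a
#' centrosome must exist to grow).
#'
#' @param V0 Initial centrosome volume (um^3), positive.
#' @param dV0 Initial volume difference (um^3), non-negative.
#' @param delta_v Subunit volume (um^3).
#' @param assignment One of `"symmetric_split"`, `"deficit_on_first"`,
#'   `"excess_on_first"`.
#' @return Integer vector `c(n1, n2)`.
#' @export
initial_counts <- function(V0, dV0 = 0, delta_v = fixed_params()$delta_v,
                           assignment = c("symmetric_split", "deficit_on_first",
                                          "excess_on_first")) {
  assignment <- match.arg(assignment)
  stopifnot(V0 > 0, dV0 >= 0, delta_v > 0)
  v <- switch(assignment,
    symmetric_split = {
      if (dV0 >= 2 * V0) stop("symmetric_split requires dV0 < 2*V0")
      c(V0 + dV0 / 2, V0 - dV0 / 2)
    },
    deficit_on_first = {
      if (dV0 >= V0) stop("deficit_on_first requires dV0 < V0")
      c(V0 - dV0, V0)
    },
    excess_on_first = c(V0 + dV0, V0)
  )
  if (any(v <= 0)) stop("initial assignment produces a non-positive volume")
  # snap away float error before the half-to-even round
  n <- round(round(v / delta_v, 9))
  pmax(n, 1L)
}
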