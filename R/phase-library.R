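#' Mesophase reflection-ratio library
#'
#' Returns the powder-pattern indexing table for the lyotropic mesophases
#' encountered in SPC/GDO depots. Each row holds the ordered ladder of
#' relative reflection positions `q_i / q_1` together with Miller labels
#' and the constant `K` of the lattice rule `a = K / q_1` mapping the
#' first reflection to the lattice parameter:
#'
#' * `Fd3m` reverse micellar cubic: ratios `sqrt((3,8,11,12,16,19,24,27)/3)`,
#'   first reflection (111), `a = 2 pi sqrt(3) / q_111`.
#' * `Pm3n` micellar cubic: ratios `sqrt((2,4,5,6,8,10)/2)`, first
#'   reflection (110), `a = 2 pi sqrt(2) / q_110`.
#' * `H2` reverse hexagonal: ratios `1, sqrt(3), 2, sqrt(7)`,
#'   `a = 4 pi / (sqrt(3) q_10)`.
#' * `lamellar`: ratios `1, 2, 3`, repeat distance `d = 2 pi / q_1`.
#'
#' The isotropic reverse micellar liquid (L2) shows no Bragg peaks and is
#' handled as a fallback classification by [index_phases()], not as a
#' library entry.
#'
#' @return A tibble with columns `phase`, `ratios` (list of numeric),
#'   `labels` (list of character) and `lattice_k` (numeric).
#' @examples
#' phase_library()
#' @export
phase_library <- function() {
  tibble::tibble(
    phase = c("Fd3m", "Pm3n", "H2", "lamellar"),
    ratios = list(
      sqrt(c(3, 8, 11, 12, 16, 19, 24, 27) / 3),
      sqrt(c(2, 4, 5, 6, 8, 10) / 2),
      c(1, sqrt(3), 2, sqrt(7)),
      c(1, 2, 3)
    ),
    labels = list(
      c("111", "220", "311", "222", "400", "331", "422", "511"),
      c("110", "200", "210", "211", "220", "310"),
      c("10", "11", "20", "21"),
      c("001", "002", "003")
    ),
    lattice_k = c(2 * pi * sqrt(3), 2 * pi * sqrt(2), 4 * pi / sqrt(3), 2 * pi)
  )
}

#' Position of a phase's first reflection
#'
#' Inverse of the lattice rule: `q_1 = K / a` for the given phase.
#'
#' @param phase Phase name present in [phase_library()].
#' @param lattice_a Lattice parameter in Angstrom.
#' @return First-reflection position in 1/Angstrom.
#' @examples
#' first_reflection_q("Fd3m", 172) # the (111) position
#' @export
first_reflection_q <- function(phase, lattice_a) {
  lib <- phase_library()
  i <- match(phase, lib$phase)
  if (is.na(i)) abort(paste0("unknown phase '", phase, "'"))
  stopifnot(all(lattice_a > 0))
  lib$lattice_k[i] / lattice_a
}

#' Lattice parameter from a first-reflection position
#'
#' @param phase Phase name present in [phase_library()].
#' @param q1 First-reflection position in 1/Angstrom.
#' @return Lattice parameter in Angstrom.
#' @export
lattice_from_q <- function(phase, q1) {
  lib <- phase_library()
  i <- match(phase, lib$phase)
  if (is.na(i)) abort(paste0("unknown phase '", phase, "'"))
  stopifnot(all(q1 > 0))
  lib$lattice_k[i] / q1
}
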