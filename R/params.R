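#' Walk generation parameters
#'
#' Bundles the parameters controlling SRRW generation. The folding
#' parameter `alpha` must exceed 1 for the jump-length distribution to be
#' normalizable; it controls the frequency of return steps and the tail of
#' the jump lengths. Lengths are in nm except `local_cutoff`, expressed in
#' units of `unit_length` (10 nm, the nucleosome scale).
#'
#' Either `n_beads` or an overall volume fraction `phi` must be given; the
#' two are related through \eqn{\phi = N (r_0 / R_c)^3} with bead radius
#' \eqn{r_0} (see [phi_to_n_beads()]).
#'
#' @param alpha folding parameter, > 1.
#' @param n_beads number of walk vertices (>= 2); computed from `phi` when
#'   missing.
#' @param phi overall volume fraction, used to derive `n_beads` when that
#'   is missing.
#' @param rc_confine global spherical cutoff radius (nm), measured from
#'   the center of mass of the already-generated vertices.
#' @param unit_length minimum jump length (nm).
#' @param local_cutoff maximum jump length, in units of `unit_length`.
#' @param bead_radius non-overlap bead radius (nm), used by the `phi`
#'   relation and downstream excluded-volume steps.
#' @param seed RNG seed recorded with the parameters; [generate_walk()]
#'   sets it before drawing.
#' @return An object of class `srev_params`.
#' @examples
#' p <- srev_params(alpha = 1.15, phi = 0.12, rc_confine = 162)
#' p$n_beads
#' @export
srev_params <- function(alpha, n_beads = NULL, phi = NULL,
                        rc_confine = 650, unit_length = 10,
                        local_cutoff = 30, bead_radius = 4.9, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 1)
    stop("`alpha` must be a single number > 1")
  if (is.null(n_beads)) {
    if (is.null(phi)) stop("supply either `n_beads` or `phi`")
    n_beads <- phi_to_n_beads(phi, rc_confine, bead_radius)
  }
  n_beads <- as.integer(n_beads)
  if (n_beads < 2L) stop("`n_beads` must be >= 2")
  if (rc_confine <= unit_length)
    stop("`rc_confine` must exceed `unit_length`")
  if (local_cutoff <= 1) stop("`local_cutoff` must be > 1 (units)")
  structure(
    list(alpha = alpha, n_beads = n_beads, rc_confine = rc_confine,
         unit_length = unit_length, local_cutoff = local_cutoff,
         bead_radius = bead_radius, seed = as.integer(seed)),
    class = "srev_params")
}

#' @export
print.srev_params <- function(x, ...) {
  cat(sprintf(
    "SRRW parameters: alpha = %.3f, N = %d (phi = %.3f), Rc = %g nm\n",
    x$alpha, x$n_beads, n_beads_to_phi(x$n_beads, x$rc_confine,
                                       x$bead_radius),
    x$rc_confine))
  cat(sprintf("  unit length %g nm, local cutoff %g units, seed %d\n",
              x$unit_length, x$local_cutoff, x$seed))
  invisible(x)
}

#' Bead count for a target volume fraction
#'
#' Inverts \eqn{\phi = N (r_0 / R_c)^3}: the number of beads of radius
#' `r0` whose total volume fills fraction `phi` of the confinement sphere
#' of radius `rc`.
#'
#' @param phi overall volume fraction.
#' @param rc confinement radius (nm).
#' @param r0 bead radius (nm).
#' @return Integer bead count (rounded).
#' @examples
#' phi_to_n_beads(0.16) # 373,483 beads at full scale
#' @export
phi_to_n_beads <- function(phi, rc = 650, r0 = 4.9) {
  if (phi <= 0) stop("`phi` must be positive")
  as.integer(round(phi * (rc / r0)^3))
}

#' @rdname phi_to_n_beads
#' @param n bead count.
#' @export
n_beads_to_phi <- function(n, rc = 650, r0 = 4.9) n * (r0 / rc)^3
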