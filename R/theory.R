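# Closed-form layer: the firing/replication time-scale competition and the
# Imax scaling law. All rates in kb and min; use kb_to_mb() for Mb^-1 min^-1.

#' Critical free-factor threshold NFD*
#'
#' The density of potential origins over unreplicated DNA stays constant as
#' long as the time to fire an origin, `1/(kon * NFD)`, exceeds the time for
#' a fork to replicate the distance `d` between neighbouring origins, `d/v`.
#' The crossover defines `NFD* = v / (kon * d)`; with `d = 1/rho0` this is
#' `v * rho0 / kon`.
#'
#' @param v Fork speed, kb/min.
#' @param kon Interaction rate, min^-1 (> 0).
#' @param d Mean distance between unreplicated origins, kb (> 0); use
#'   `1/rho0` unless an empirical value is available.
#' @return NFD* (count of firing factors).
#' @examples
#' critical_free_factors(0.6, 6e-3, 1 / 0.28)  # 28
#' @export
critical_free_factors <- function(v, kon, d) {
  if (any(kon <= 0) || any(d <= 0)) {
    abort("kon and d must be positive", class = "replikin_param_error")
  }
  v / (kon * d)
}

#' Predicted maximum firing rate, Imax = v * rho0^2
#'
#' At the I(t) maximum the free-factor count reaches `NFD*`, giving
#' `Imax = kon * rho0 * NFD* ~ v * rho0^2` (with `d ~ 1/rho0`, exact for
#' periodically spaced origins). Imax is therefore predicted from two
#' directly measurable quantities, fork speed and potential-origin density.
#'
#' @inheritParams critical_free_factors
#' @param rho0 Initial potential-origin density, kb^-1.
#' @return Imax in kb^-1 min^-1.
#' @examples
#' predicted_imax(0.6, 0.28)
#' kb_to_mb(predicted_imax(1.5, 829 / 12500))  # ~6.6 Mb^-1 min^-1
#' @export
predicted_imax <- function(v, rho0) {
  stopifnot(all(v >= 0), all(rho0 >= 0))
  v * rho0^2
}

#' Bimolecular firing rate per unreplicated length
#'
#' `I(t) = kon * NFD(t) * rho(t)` where `rho(t)` is the density of potential
#' origins over unreplicated DNA.
#'
#' @inheritParams critical_free_factors
#' @param nfd Free firing-factor count.
#' @param rho Potential-origin density over unreplicated DNA, kb^-1.
#' @return Rate in kb^-1 min^-1.
#' @export
bimolecular_rate <- function(kon, nfd, rho) {
  stopifnot(all(kon >= 0), all(nfd >= 0), all(rho >= 0))
  kon * nfd * rho
}

#' Density regime of the origin pool
#'
#' Classifies a parameter point: `"constant-density"` when
#' `d/v < 1/(kon*NFD)` (equivalently `NFD < NFD*`), i.e. passivation keeps
#' pace and the origin density over unreplicated DNA holds steady;
#' `"density-depleting"` otherwise, when firing outruns fork progress and
#' the density — and with it I(t) — must fall.
#'
#' @inheritParams critical_free_factors
#' @param nfd Free firing-factor count.
#' @return `"constant-density"` or `"density-depleting"`.
#' @export
density_criterion <- function(v, kon, nfd, d) {
  star <- critical_free_factors(v, kon, d)
  ifelse(nfd < star, "constant-density", "density-depleting")
}

#' Two-compartment upper bound on Imax
#'
#' For a genome split between early-replicating domains of high origin
#' density `rho_early` and late domains of negligible density, each covering
#' about half the genome, firing is dominated by the early compartment while
#' the unreplicated length includes both, so `Imax <= 0.5 * v * rho_early^2`.
#'
#' @inheritParams predicted_imax
#' @param rho_early Origin density in early-replicating domains, kb^-1.
#' @return Bound in kb^-1 min^-1.
#' @export
two_compartment_imax <- function(v, rho_early) {
  stopifnot(all(v >= 0), all(rho_early >= 0))
  0.5 * v * rho_early^2
}

#' Convert kb^-1 min^-1 to Mb^-1 min^-1
#' @param x Rate in kb^-1 min^-1.
#' @return Rate in Mb^-1 min^-1.
#' @export
kb_to_mb <- function(x) 1000 * x
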