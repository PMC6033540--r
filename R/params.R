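#' Simulation parameter set
#'
#' Bundles the well-mixed model parameters: genome, fork speed `v` (kb/min),
#' productive-interaction rate `kon` (min^-1), total number of firing factors
#' `ndt`, exponential loading timescale `tau_load` (min), and the time step
#' `dt` (min).
#'
#' Each firing factor becomes available at an exponentially distributed time
#' with mean `tau_load` ("exponentially relaxed loading"); after loading the
#' total pool is constant. With `ndt_mode = "poisson"` each run of an
#' ensemble draws its own pool size from a Poisson of mean `ndt`, emulating
#' cell-to-cell variability. Forks that reach a chromosome end are discarded;
#' by default the half factor they carry is lost, with `recycle_at_ends =
#' TRUE` end halves re-pair into free factors.
#'
#' @param genome A [genome_spec()].
#' @param v Fork speed, kb/min (> 0).
#' @param kon Productive-interaction rate, min^-1 (>= 0); `kon * dt` must not
#'   exceed 1.
#' @param ndt Total firing-factor count (>= 0).
#' @param tau_load Loading timescale, min (>= 0; 0 = instantaneous).
#' @param dt Time step, min (default 0.01). A warning is issued when `v * dt`
#'   exceeds half the minimum inter-origin spacing.
#' @param ndt_mode `"constant"` or `"poisson"` (per-run Poisson pool size).
#' @param recycle_at_ends Recycle half factors from end-discarded forks
#'   (paired) instead of losing them.
#' @param loading `"stochastic"` (i.i.d. exponential arrivals) or
#'   `"deterministic"` (arrival times chosen so the loaded count tracks
#'   `round(ndt * (1 - exp(-t/tau)))`; useful for variance reduction).
#' @param max_time Guard against non-termination (min); exceeded only in
#'   degenerate setups such as `ndt = 0`.
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(genome_periodic(3000, 0.28), v = 0.6, kon = 6e-3,
#'                 ndt = 165, tau_load = 3)
#' p
#' @export
sim_params <- function(genome, v, kon, ndt, tau_load = 0, dt = 0.01,
                       ndt_mode = c("constant", "poisson"),
                       recycle_at_ends = FALSE,
                       loading = c("stochastic", "deterministic"),
                       max_time = 1e5) {
  stopifnot(inherits(genome, "genome_spec"))
  ndt_mode <- match.arg(ndt_mode)
  loading <- match.arg(loading)
  if (v <= 0 || kon < 0 || ndt < 0 || tau_load < 0 || dt <= 0) {
    abort("need v > 0, kon >= 0, ndt >= 0, tau_load >= 0, dt > 0",
          class = "replikin_param_error")
  }
  if (kon * dt > 1) {
    abort("kon * dt > 1: time step too coarse for the firing probability",
          class = "replikin_param_error")
  }
  if (nrow(genome$origins) > 1) {
    gaps <- unlist(tapply(genome$origins$position, genome$origins$chrom,
                          function(x) diff(sort(x))), use.names = FALSE)
    if (length(gaps) && v * dt > min(gaps) / 2) {
      warn(sprintf(
        "v*dt = %.3g kb exceeds half the minimum origin spacing (%.3g kb)",
        v * dt, min(gaps)))
    }
  }
  structure(list(genome = genome, v = v, kon = kon, ndt = as.integer(round(ndt)),
                 tau_load = tau_load, dt = dt, ndt_mode = ndt_mode,
                 recycle_at_ends = recycle_at_ends, loading = loading,
                 max_time = max_time),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> v = %g kb/min, kon = %g /min, NDT = %d (%s), tau = %g min, dt = %g min\n",
    x$v, x$kon, x$ndt, x$ndt_mode, x$tau_load, x$dt))
  print(x$genome)
  invisible(x)
}

#' Sample firing-factor arrival times
#'
#' Arrival times of the `ndt` firing factors under exponentially relaxed
#' loading with timescale `tau_load`: i.i.d. exponential for
#' `loading = "stochastic"`, or deterministic times placed so the loaded
#' count tracks `round(ndt * (1 - exp(-t / tau_load)))`. `tau_load = 0`
#' makes all factors available at t = 0.
#'
#' @inheritParams sim_params
#' @return Sorted numeric vector of arrival times (min), length `ndt`.
#' @export
sample_factor_arrivals <- function(ndt, tau_load,
                                   loading = c("stochastic", "deterministic")) {
  loading <- match.arg(loading)
  if (ndt < 0 || tau_load < 0) {
    abort("ndt and tau_load must be non-negative",
          class = "replikin_param_error")
  }
  ndt <- as.integer(round(ndt))
  if (ndt == 0) return(numeric(0))
  if (tau_load == 0) return(numeric(ndt))
  if (loading == "stochastic") {
    sort(rexp(ndt, rate = 1 / tau_load))
  } else {
    -tau_load * log(1 - (seq_len(ndt) - 0.5) / ndt)
  }
}

#' Per-step origin firing probability
#'
#' Probability that one free firing factor fires some potential origin within
#' a step of length `dt`, when `n_pori` potential origins remain:
#' `1 - (1 - kon*dt)^n_pori`. Monotone non-decreasing in every argument.
#'
#' @inheritParams sim_params
#' @param n_pori Number of potential origins at unreplicated loci.
#' @return Probability in `[0, 1]` (vectorised over `n_pori`).
#' @examples
#' firing_probability(6e-3, 0.01, 840)
#' @export
firing_probability <- function(kon, dt, n_pori) {
  if (kon < 0 || dt < 0 || kon * dt > 1 || any(n_pori < 0)) {
    abort("need 0 <= kon*dt <= 1 and n_pori >= 0",
          class = "replikin_param_error")
  }
  -expm1(n_pori * log1p(-kon * dt))
}

#' Rescale simulation parameters at fixed replication kinetics
#'
#' Applies the invariance transformation `L -> alpha*L`, `NDT -> alpha*NDT`,
#' `kon -> kon/alpha` (origin density `rho0` preserved), which leaves the
#' firing rate I(t) and the S-phase duration `T ~ L / (2 v NDT)` unchanged.
#' Used to shrink huge genomes to tractable simulated lengths.
#'
#' @param params A [sim_params()].
#' @param alpha Positive scale factor; a warning is issued when `alpha * ndt`
#'   is not an integer (it is rounded).
#' @return A new `sim_params`.
#' @export
rescale_parameters <- function(params, alpha) {
  stopifnot(inherits(params, "sim_params"))
  if (alpha <= 0) {
    abort("alpha must be positive", class = "replikin_param_error")
  }
  if (abs(alpha * params$ndt - round(alpha * params$ndt)) > 1e-9) {
    warn(sprintf("alpha * ndt = %g is not an integer; rounding",
                 alpha * params$ndt))
  }
  g <- params$genome
  if (g$resample == "uniform") {
    genome <- genome_uniform(sum(g$chromosomes$length) * alpha, g$rho0)
  } else if (g$resample == "periodic") {
    genome <- genome_periodic(sum(g$chromosomes$length) * alpha, g$rho0)
  } else {
    # fixed maps: tile each chromosome's origins alpha times (integer alpha)
    if (abs(alpha - round(alpha)) > 1e-9) {
      abort("fixed origin maps can only be rescaled by integer alpha",
            class = "replikin_param_error")
    }
    a <- round(alpha)
    chroms <- dplyr::mutate(g$chromosomes, length = .data$length * a)
    len0 <- setNames(g$chromosomes$length, g$chromosomes$chrom)
    tiled <- purrr::map_dfr(seq_len(a) - 1, function(k) {
      dplyr::mutate(g$origins,
                    position = .data$position + k * len0[.data$chrom])
    })
    genome <- genome_spec(chroms, tiled)
  }
  sim_params(genome, v = params$v, kon = params$kon / alpha,
             ndt = round(params$ndt * alpha), tau_load = params$tau_load,
             dt = params$dt, ndt_mode = params$ndt_mode,
             recycle_at_ends = params$recycle_at_ends,
             loading = params$loading, max_time = params$max_time)
}
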