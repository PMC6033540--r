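# Global (concatenated-chromosome) coordinates used by the event loop:
# chromosomes laid end to end, forks discarded at the internal boundaries
# exactly as at physical chromosome ends.
genome_layout <- function(genome) {
  len <- genome$chromosomes$length
  ends <- cumsum(len)
  offsets <- setNames(c(0, head(ends, -1)), genome$chromosomes$chrom)
  o <- genome$origins
  list(chrom_ends = ends,
       offsets = offsets,
       ori_pos = if (nrow(o)) sort(o$position + offsets[o$chrom]) else numeric(0))
}

# map sorted global origin positions back to the origin table ordering
origins_with_lifecycle <- function(genome, layout, ori_status, ori_event_time) {
  o <- genome$origins
  if (nrow(o) == 0) {
    return(tibble(chrom = character(), position = numeric(),
                  status = character(), lifecycle = character(),
                  event_time = numeric()))
  }
  gpos <- o$position + layout$offsets[o$chrom]
  idx <- match(round(gpos, 9), round(layout$ori_pos, 9))
  tibble(chrom = o$chrom, position = o$position, status = o$status,
         lifecycle = c("potential", "fired", "passivated")[ori_status[idx] + 1L],
         event_time = ori_event_time[idx])
}

#' Simulate one S-phase
#'
#' Runs the well-mixed stochastic event loop until all DNA is replicated.
#' Every step applies, in order: firing-factor arrivals, firing attempts
#' (each free factor fires with probability
#' `1 - (1 - kon*dt)^Npori`, a fired origin is chosen uniformly among the
#' remaining potential origins and spawns two diverging forks), then fork
#' propagation by `v*dt` with passivation of swept origins, pairwise removal
#' of converging forks (releasing one free factor per merger) and discard of
#' forks reaching a chromosome end.
#'
#' @param params A [sim_params()].
#' @param seed Optional integer seed (`set.seed()` is called when given;
#'   otherwise the current RNG state is used).
#' @param record_kinetics Keep the per-step time series (default `TRUE`).
#' @return An object of class `sphase_record`: a list with
#'   \describe{
#'     \item{kinetics}{tibble with one row per step: `time` (min, step
#'       start), `nfd` (free factors after arrivals), `n_pori`, `l_unrep`
#'       (kb, at step start), `n_fired`, `n_passivated` (events in the step).}
#'     \item{origins}{origin table with final `lifecycle`
#'       (fired/passivated) and `event_time`.}
#'     \item{replication_time}{completion time (min).}
#'     \item{counters}{list: `n_fired`, `n_passivated`, `n_merges`,
#'       `n_loaded`, `n_free_final`, `lost_halves`.}
#'   }
#' @examples
#' p <- sim_params(genome_periodic(300, 0.28), v = 0.6, kon = 6e-3,
#'                 ndt = 20, tau_load = 3)
#' rec <- simulate_sphase(p, seed = 1)
#' rec$replication_time
#' @export
simulate_sphase <- function(params, seed = NULL, record_kinetics = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  lay <- genome_layout(params$genome)
  arrivals <- sample_factor_arrivals(params$ndt, params$tau_load,
                                     params$loading)
  res <- sim_sphase_cpp(lay$ori_pos, lay$chrom_ends, params$v, params$kon,
                        arrivals, params$dt, params$recycle_at_ends,
                        params$max_time, record_kinetics)
  new_sphase_record(res, params, lay)
}

new_sphase_record <- function(res, params, lay) {
  structure(
    list(kinetics = as_tibble(res$kinetics),
         origins = origins_with_lifecycle(params$genome, lay, res$status,
                                          res$event_time),
         replication_time = res$replication_time,
         counters = res[c("n_fired", "n_passivated", "n_merges", "n_loaded",
                          "n_free_final", "lost_halves")],
         params = params),
    class = "sphase_record")
}

#' @export
print.sphase_record <- function(x, ...) {
  cat(sprintf(
    "<sphase_record> T = %.2f min; %d fired, %d passivated, %d mergers\n",
    x$replication_time, x$counters$n_fired, x$counters$n_passivated,
    x$counters$n_merges))
  invisible(x)
}

#' Simulate an ensemble of independent S-phases
#'
#' Runs `n_runs` independent S-phases with per-run seeds derived
#' deterministically from `seed` (a fixed `sample.int()` draw under
#' `set.seed(seed)`), so the full ensemble is reproducible across machines.
#' For genomes built with `resample = "uniform"`/`"periodic"` each run
#' re-draws the origin positions; file-based maps stay fixed. With
#' `ndt_mode = "poisson"` each run draws its pool size from a Poisson of
#' mean `ndt`.
#'
#' @inheritParams simulate_sphase
#' @param n_runs Number of independent S-phases (>= 1).
#' @param seed Master seed (integer). Same seed, same ensemble.
#' @param record_kinetics Keep per-run kinetics (needed for I(t) pooling).
#' @return An object of class `replication_ensemble`: list with `runs`
#'   (per-run summary tibble), `kinetics` (list of per-run kinetics tibbles,
#'   if recorded), `rho0_runs` (per-run initial density), `params`, `n_runs`.
#' @examples
#' p <- sim_params(genome_periodic(300, 0.28), v = 0.6, kon = 6e-3,
#'                 ndt = 20, tau_load = 3)
#' ens <- simulate_ensemble(p, n_runs = 5, seed = 42)
#' glance(ens)
#' @export
simulate_ensemble <- function(params, n_runs, seed = NULL,
                              record_kinetics = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (n_runs < 1) {
    abort("n_runs must be >= 1", class = "replikin_param_error")
  }
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)
  g <- params$genome
  L <- sum(g$chromosomes$length)
  runs <- vector("list", n_runs)
  kin <- if (record_kinetics) vector("list", n_runs) else NULL
  fired_times <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    pr <- params
    if (params$ndt_mode == "poisson") {
      pr$ndt <- rpois(1, params$ndt)
    }
    if (g$resample == "uniform") {
      pr$genome <- genome_uniform(L, g$rho0)
    } else if (g$resample == "periodic") {
      pr$genome <- genome_periodic(L, g$rho0)
    }
    rec <- simulate_sphase(pr, seed = NULL, record_kinetics = record_kinetics)
    if (record_kinetics) kin[[r]] <- rec$kinetics
    fired <- rec$origins$event_time[rec$origins$lifecycle == "fired"]
    fired_times[[r]] <- fired
    runs[[r]] <- tibble(
      run = r, seed = run_seeds[r], ndt = pr$ndt,
      n_pori0 = nrow(pr$genome$origins),
      replication_time = rec$replication_time,
      n_fired = rec$counters$n_fired,
      n_passivated = rec$counters$n_passivated,
      n_merges = rec$counters$n_merges)
  }
  structure(
    list(runs = dplyr::bind_rows(runs), kinetics = kin,
         fired_times = fired_times, params = params, n_runs = n_runs,
         genome_length = L),
    class = "replication_ensemble")
}

#' @export
print.replication_ensemble <- function(x, ...) {
  cat(sprintf(
    "<replication_ensemble> %d runs; T = %.2f +/- %.2f min; mean fired = %.1f\n",
    x$n_runs, mean(x$runs$replication_time), sd(x$runs$replication_time),
    mean(x$runs$n_fired)))
  invisible(x)
}
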