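#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a replication ensemble
#'
#' One row per simulated S-phase: seed, factor pool size, initial origin
#' count, completion time and event counts.
#'
#' @param x A `replication_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.replication_ensemble <- function(x, ...) {
  x$runs
}

#' One-row ensemble summary
#'
#' Reports the ensemble-level quantities of interest: mean and sd of the
#' replication time, mean fired and passivated origin counts, the activated
#' origin density, and the potential-origin density.
#'
#' @param x A `replication_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.replication_ensemble <- function(x, ...) {
  tibble(n_runs = x$n_runs,
         replication_time_mean = mean(x$runs$replication_time),
         replication_time_sd = if (x$n_runs > 1) sd(x$runs$replication_time)
                               else NA_real_,
         n_fired_mean = mean(x$runs$n_fired),
         n_passivated_mean = mean(x$runs$n_passivated),
         activated_density = activated_origin_density(x),
         rho0 = mean(x$runs$n_pori0) / x$genome_length)
}

#' Tidy one S-phase record
#'
#' Returns the per-step kinetics series as a tibble.
#'
#' @param x An `sphase_record`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sphase_record <- function(x, ...) {
  x$kinetics
}

#' One-row S-phase summary
#' @param x An `sphase_record`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.sphase_record <- function(x, ...) {
  tibble(replication_time = x$replication_time,
         n_fired = x$counters$n_fired,
         n_passivated = x$counters$n_passivated,
         n_merges = x$counters$n_merges,
         n_loaded = x$counters$n_loaded)
}
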