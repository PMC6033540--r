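#' Firing rate per unreplicated length, I(t), for one run
#'
#' Bins one S-phase record and computes, per bin, the firing rate per length
#' of unreplicated DNA: `I = (number fired) / (sum of l_unrep * dt)`. Bins
#' with no unreplicated DNA throughout are dropped.
#'
#' @param record An `sphase_record` from [simulate_sphase()].
#' @param bin_width Bin width in min (must be >= the simulation `dt`).
#' @return A tibble with `time` (bin midpoint, min), `n_fired`, and `i`
#'   (kb^-1 min^-1).
#' @export
firing_rate <- function(record, bin_width) {
  stopifnot(inherits(record, "sphase_record"))
  dt <- record$params$dt
  if (bin_width < dt) {
    abort("bin_width must be >= the simulation time step",
          class = "replikin_param_error")
  }
  k <- record$kinetics
  ib <- floor(k$time / bin_width)
  agg <- rowsum(cbind(fired = k$n_fired, w = k$l_unrep * dt), ib)
  keep <- agg[, "w"] > 0
  tibble(time = (as.numeric(rownames(agg)) + 0.5) * bin_width,
         n_fired = unname(agg[, "fired"]),
         i = unname(ifelse(keep, agg[, "fired"] / agg[, "w"],
                           NA_real_)))[keep, ]
}

# per-run binned accumulators: runs x bins matrices of firing counts,
# unreplicated-length exposure, passivation counts, density and free-factor
# time integrals, and active time
bin_ensemble <- function(ensemble, bin_width) {
  dt <- ensemble$params$dt
  kin <- ensemble$kinetics
  if (is.null(kin)) {
    abort("ensemble was run with record_kinetics = FALSE",
          class = "replikin_param_error")
  }
  nb <- max(vapply(kin, function(k) floor(max(k$time) / bin_width), 0)) + 1
  acc <- function(f) {
    m <- matrix(0, length(kin), nb)
    for (r in seq_along(kin)) {
      k <- kin[[r]]
      ib <- floor(k$time / bin_width) + 1
      v <- rowsum(f(k), ib)
      m[r, as.numeric(rownames(v))] <- v
    }
    m
  }
  list(F = acc(function(k) k$n_fired),
       W = acc(function(k) k$l_unrep * dt),
       P = acc(function(k) k$n_passivated),
       RHO = acc(function(k) k$n_pori * dt),
       NFD = acc(function(k) k$nfd * dt),
       A = acc(function(k) rep(dt, nrow(k))),
       nb = nb)
}

#' Pooled ensemble kinetics
#'
#' Pools an ensemble of S-phase records into the standard observables on a
#' common time grid. The firing rate is a ratio of sums across runs,
#' `I = (sum fired) / (sum l_unrep * dt)`, which stays well-behaved when
#' individual runs approach full replication; its standard error comes from
#' a seeded run-level bootstrap. Also reported per bin: the mean density of
#' potential origins over unreplicated DNA normalized by the initial density
#' (`rho_norm`), the mean free-factor count normalized by the critical
#' threshold `NFD* = v * rho0 / kon` (`nfd_norm`), the
#' passivation/activation ratio (`NA` in bins without activations), and the
#' ensemble-mean unreplicated fraction.
#'
#' @param ensemble A `replication_ensemble`.
#' @param bin_width Bin width in min.
#' @param n_boot Bootstrap resamples for the I(t) standard error.
#' @param boot_seed Seed for the bootstrap (the caller's RNG state is
#'   restored afterwards).
#' @return A tibble of class `ensemble_kinetics` with columns `time`, `i`,
#'   `i_se`, `rho_norm`, `nfd_norm`, `pass_act_ratio`, `n_fired`,
#'   `n_passivated`, `unrep_frac`; attributes carry `bin_width`, `n_runs`,
#'   `rho0`, `nfd_star` and the genome length.
#' @export
ensemble_kinetics <- function(ensemble, bin_width, n_boot = 200,
                              boot_seed = 1L) {
  stopifnot(inherits(ensemble, "replication_ensemble"))
  p <- ensemble$params
  if (bin_width < p$dt) {
    abort("bin_width must be >= the simulation time step",
          class = "replikin_param_error")
  }
  b <- bin_ensemble(ensemble, bin_width)
  L <- ensemble$genome_length
  rho0 <- mean(ensemble$runs$n_pori0) / L
  nfd_star <- if (p$kon > 0) critical_free_factors(p$v, p$kon, 1 / rho0)
              else NA_real_
  sF <- colSums(b$F); sW <- colSums(b$W); sP <- colSums(b$P)
  sRHO <- colSums(b$RHO); sNFD <- colSums(b$NFD); sA <- colSums(b$A)
  keep <- sW > 0
  i_hat <- ifelse(keep, sF / sW, NA_real_)

  i_se <- rep(NA_real_, b$nb)
  if (n_boot > 0 && nrow(b$F) > 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(boot_seed)
    idx <- matrix(sample.int(nrow(b$F), n_boot * nrow(b$F), replace = TRUE),
                  n_boot)
    boot <- matrix(NA_real_, n_boot, b$nb)
    for (s in seq_len(n_boot)) {
      fw <- colSums(b$F[idx[s, ], , drop = FALSE])
      ww <- colSums(b$W[idx[s, ], , drop = FALSE])
      boot[s, ww > 0] <- fw[ww > 0] / ww[ww > 0]
    }
    i_se <- apply(boot, 2, sd, na.rm = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  out <- tibble(
    time = (seq_len(b$nb) - 0.5) * bin_width,
    i = i_hat,
    i_se = i_se,
    rho_norm = ifelse(keep, (sRHO / sW) / rho0, NA_real_),
    nfd_norm = ifelse(sA > 0, (sNFD / sA) / nfd_star, NA_real_),
    pass_act_ratio = ifelse(sF > 0, sP / sF, NA_real_),
    n_fired = sF,
    n_passivated = sP,
    unrep_frac = sW / (nrow(b$F) * bin_width * L))[keep | sA > 0, ]
  structure(out,
            class = c("ensemble_kinetics", class(out)),
            bin_width = bin_width, n_runs = ensemble$n_runs, rho0 = rho0,
            nfd_star = nfd_star, genome_length = L)
}

#' Maximum firing rate of a pooled ensemble
#'
#' Returns the maximum of the pooled I(t), restricted to bins where the
#' ensemble-mean unreplicated fraction exceeds `tail_exclusion` so the
#' estimate is not dominated by the small-denominator noise at the very end
#' of S-phase.
#'
#' @param kinetics An [ensemble_kinetics()] table.
#' @param tail_exclusion Minimum mean unreplicated fraction (default 0.05).
#' @return A one-row tibble: `imax` (kb^-1 min^-1), `t_imax` (bin midpoint,
#'   min), `i_se` at the maximum.
#' @export
estimate_imax <- function(kinetics, tail_exclusion = 0.05) {
  stopifnot(inherits(kinetics, "ensemble_kinetics"))
  k <- kinetics[!is.na(kinetics$i) & kinetics$unrep_frac > tail_exclusion, ]
  if (nrow(k) == 0) {
    abort("no bins left after tail exclusion",
          class = "replikin_estimation_error")
  }
  j <- which.max(k$i)
  tibble(imax = k$i[j], t_imax = k$time[j], i_se = k$i_se[j])
}

#' Passivation/activation ratio for a single run
#'
#' Per time bin, the number of passivated over the number of fired origins;
#' bins without activations are `NA` (undefined, not zero).
#'
#' @inheritParams firing_rate
#' @return A tibble with `time`, `n_fired`, `n_passivated`, `ratio`.
#' @export
passivation_activation_ratio <- function(record, bin_width) {
  stopifnot(inherits(record, "sphase_record"))
  k <- record$kinetics
  ib <- floor(k$time / bin_width)
  agg <- rowsum(cbind(fired = k$n_fired, pass = k$n_passivated), ib)
  tibble(time = (as.numeric(rownames(agg)) + 0.5) * bin_width,
         n_fired = unname(agg[, "fired"]),
         n_passivated = unname(agg[, "pass"]),
         ratio = unname(ifelse(agg[, "fired"] > 0,
                               agg[, "pass"] / agg[, "fired"], NA_real_)))
}

#' Replication-time summary of an ensemble
#'
#' @param ensemble A `replication_ensemble`.
#' @return A one-row tibble: `mean`, `sd` (min), `n_runs`.
#' @export
replication_time_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "replication_ensemble"))
  tt <- ensemble$runs$replication_time
  tibble(mean = mean(tt), sd = if (length(tt) > 1) sd(tt) else NA_real_,
         n_runs = length(tt))
}

#' Replication-time samples
#' @param ensemble A `replication_ensemble`.
#' @return Numeric vector of per-run completion times (min).
#' @export
replication_times <- function(ensemble) {
  ensemble$runs$replication_time
}

#' Mean density of activated origins
#'
#' Mean over runs of (origins fired during S-phase) / (genome length).
#' Always bounded above by the potential-origin density `rho0`.
#'
#' @param ensemble A `replication_ensemble`.
#' @return Density in kb^-1.
#' @export
activated_origin_density <- function(ensemble) {
  stopifnot(inherits(ensemble, "replication_ensemble"))
  mean(ensemble$runs$n_fired) / ensemble$genome_length
}
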