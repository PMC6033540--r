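# Explicit replication-state objects and single-step transitions.
#
# This is a plain-R mirror of the compiled event loop, kept primarily as the
# testable specification of the per-step semantics (firing, propagation,
# passivation, merger, end discard, factor bookkeeping). It consumes the RNG
# in exactly the same order as the compiled loop, so composing sim_step()
# from the same seed reproduces simulate_sphase() record for record.

#' Initial replication state
#'
#' Builds the time-zero state for the well-mixed event loop: no replicated
#' DNA, all origins potential, factor arrival times pre-drawn.
#'
#' @param params A [sim_params()].
#' @return An object of class `replication_state` (a list): `time`,
#'   replicated `intervals` (`s`, `e`, `la`, `ra` — start/end in global kb and
#'   left/right fork-active flags), origin bookkeeping, and the factor pool
#'   (`n_free`, `bound_halves`, `lost_halves`, `n_loaded`).
#' @export
replication_state <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  lay <- genome_layout(params$genome)
  n <- length(lay$ori_pos)
  structure(list(
    time = 0,
    intervals = list(s = numeric(0), e = numeric(0),
                     la = logical(0), ra = logical(0)),
    ori_pos = lay$ori_pos,
    ori_status = integer(n),            # 0 potential, 1 fired, 2 passivated
    ori_event_time = rep(NA_real_, n),
    pot_idx = seq_len(n),
    chrom_ends = lay$chrom_ends,
    arrivals = sample_factor_arrivals(params$ndt, params$tau_load,
                                      params$loading),
    arr_ptr = 0L,
    n_free = 0L, bound_halves = 0L, lost_halves = 0L, spare_halves = 0L,
    n_loaded = 0L, n_fired = 0L, n_passivated = 0L, n_merges = 0L),
    class = "replication_state")
}

state_l_replicated <- function(state) {
  sum(state$intervals$e - state$intervals$s)
}

#' Total unreplicated DNA of a state
#' @param state A [replication_state()].
#' @return Length in kb.
#' @export
l_unreplicated <- function(state) {
  tail(state$chrom_ends, 1) - state_l_replicated(state)
}

state_chrom_of <- function(state, x) {
  findInterval(x + 1e-12, state$chrom_ends) + 1L
}

apply_arrivals <- function(state) {
  while (state$arr_ptr < length(state$arrivals) &&
         state$arrivals[state$arr_ptr + 1L] <= state$time + 1e-12) {
    state$n_free <- state$n_free + 1L
    state$n_loaded <- state$n_loaded + 1L
    state$arr_ptr <- state$arr_ptr + 1L
  }
  state
}

state_passivate <- function(state, a, b) {
  if (b < a) return(state)
  eps <- 1e-9
  hit <- which(state$ori_pos >= a - eps & state$ori_pos <= b + eps &
               state$ori_status == 0L)
  if (length(hit)) {
    state$ori_status[hit] <- 2L
    state$ori_event_time[hit] <- state$time
    state$pot_idx <- pot_swap_remove(state$pot_idx, hit)
    state$n_passivated <- state$n_passivated + length(hit)
  }
  state
}

# swap-remove, preserving the compiled loop's pot_idx ordering
pot_swap_remove <- function(pot_idx, oris) {
  for (oi in oris) {
    j <- match(oi, pot_idx)
    m <- length(pot_idx)
    pot_idx[j] <- pot_idx[m]
    pot_idx <- pot_idx[-m]
  }
  pot_idx
}

#' One round of firing attempts
#'
#' Each free firing factor independently fires with probability
#' [firing_probability()] evaluated with the potential-origin count frozen at
#' step start. Every firing marks a uniformly chosen distinct potential
#' origin as fired and creates a left- and a right-moving fork at its
#' position; the free pool decreases by one per firing. Surplus successes
#' beyond the available origins are no-ops.
#'
#' @param state A [replication_state()].
#' @param params The matching [sim_params()].
#' @return The updated state.
#' @export
attempt_firings <- function(state, params) {
  n_pot <- length(state$pot_idx)
  if (state$n_free <= 0L || n_pot == 0L || params$kon <= 0) return(state)
  p <- firing_probability(params$kon, params$dt, n_pot)
  k <- rbinom(1L, state$n_free, p)
  f <- 0L
  while (f < k && length(state$pot_idx) > 0L) {
    m <- length(state$pot_idx)
    j <- floor(runif(1) * m) + 1L
    if (j > m) j <- m
    oi <- state$pot_idx[j]
    state$pot_idx[j] <- state$pot_idx[m]
    state$pot_idx <- state$pot_idx[-m]
    state$ori_status[oi] <- 1L
    state$ori_event_time[oi] <- state$time
    state$n_fired <- state$n_fired + 1L
    state$n_free <- state$n_free - 1L
    state$bound_halves <- state$bound_halves + 2L
    x <- state$ori_pos[oi]
    iv <- state$intervals
    at <- sum(iv$s < x)                  # insert keeping s sorted
    ins <- function(v, val) append(v, val, after = at)
    state$intervals <- list(s = ins(iv$s, x), e = ins(iv$e, x),
                            la = ins(iv$la, TRUE), ra = ins(iv$ra, TRUE))
    f <- f + 1L
  }
  state
}

discard_half <- function(state) {
  state$bound_halves <- state$bound_halves - 1L
  if (isTRUE(state$recycle_at_ends_flag)) {
    state$spare_halves <- state$spare_halves + 1L
    if (state$spare_halves == 2L) {
      state$spare_halves <- 0L
      state$n_free <- state$n_free + 1L
    }
  } else {
    state$lost_halves <- state$lost_halves + 1L
  }
  state
}

#' Propagate all forks by one step
#'
#' Moves every active fork by `v*dt`, marks swept DNA replicated, passivates
#' potential origins inside newly replicated intervals, removes converging
#' fork pairs (their firing factor reforms: free pool +1 per merger) and
#' discards forks that reach a chromosome end.
#'
#' @inheritParams attempt_firings
#' @return The updated state.
#' @export
advance_forks <- function(state, params) {
  eps <- 1e-9
  step_len <- params$v * params$dt
  state$recycle_at_ends_flag <- params$recycle_at_ends
  iv <- state$intervals
  for (i in seq_along(iv$s)) {
    ci <- state_chrom_of(state, iv$s[i])
    cs <- if (ci > 1) state$chrom_ends[ci - 1] else 0
    ce <- state$chrom_ends[ci]
    if (iv$la[i]) {
      olds <- iv$s[i]
      iv$s[i] <- iv$s[i] - step_len
      if (iv$s[i] <= cs + eps) {
        iv$s[i] <- cs
        iv$la[i] <- FALSE
        state <- discard_half(state)
      }
      state <- state_passivate(state, iv$s[i], olds)
    }
    if (iv$ra[i]) {
      olde <- iv$e[i]
      iv$e[i] <- iv$e[i] + step_len
      if (iv$e[i] >= ce - eps) {
        iv$e[i] <- ce
        iv$ra[i] <- FALSE
        state <- discard_half(state)
      }
      state <- state_passivate(state, olde, iv$e[i])
    }
  }
  # mergers, cascading left to right
  i <- 1L
  while (length(iv$s) > 1L && i < length(iv$s)) {
    same_chrom <- state_chrom_of(state, iv$s[i]) ==
      state_chrom_of(state, iv$s[i + 1])
    if (same_chrom && iv$s[i + 1] <= iv$e[i] + eps) {
      if (iv$ra[i] && iv$la[i + 1]) {
        state$n_free <- state$n_free + 1L
        state$bound_halves <- state$bound_halves - 2L
        state$n_merges <- state$n_merges + 1L
      }
      iv$e[i] <- max(iv$e[i], iv$e[i + 1])
      iv$ra[i] <- iv$ra[i + 1]
      iv <- lapply(iv, function(v) v[-(i + 1)])
    } else {
      i <- i + 1L
    }
  }
  state$intervals <- iv
  state
}

#' One full time step
#'
#' Applies, in order: newly arrived factors, [attempt_firings()],
#' [advance_forks()]; then advances time by `dt`.
#'
#' @inheritParams attempt_firings
#' @return The updated state.
#' @export
sim_step <- function(state, params) {
  state <- apply_arrivals(state)
  state <- attempt_firings(state, params)
  state <- advance_forks(state, params)
  state$time <- state$time + params$dt
  state
}

#' Run a full S-phase through the step-level reference implementation
#'
#' Composes [sim_step()] until all DNA is replicated, recording the same
#' per-step series as [simulate_sphase()]. Intended for validation on small
#' systems; the compiled loop is the production path.
#'
#' @inheritParams simulate_sphase
#' @return An `sphase_record`.
#' @export
simulate_sphase_reference <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- replication_state(params)
  L <- tail(state$chrom_ends, 1)
  rows <- list()
  k <- 0L
  while (l_unreplicated(state) > 1e-9) {
    if (state$time > params$max_time) {
      abort("replication did not complete before max_time",
            class = "replikin_runtime_error")
    }
    fired0 <- state$n_fired; pass0 <- state$n_passivated
    state <- apply_arrivals(state)
    snap <- c(time = state$time, nfd = state$n_free,
              n_pori = length(state$pot_idx),
              l_unrep = l_unreplicated(state))
    state <- attempt_firings(state, params)
    state <- advance_forks(state, params)
    state$time <- state$time + params$dt
    k <- k + 1L
    rows[[k]] <- c(snap, n_fired = state$n_fired - fired0,
                   n_passivated = state$n_passivated - pass0)
  }
  kin <- as_tibble(as.data.frame(do.call(rbind, rows)))
  lay <- genome_layout(params$genome)
  res <- list(kinetics = kin, status = state$ori_status,
              event_time = state$ori_event_time,
              replication_time = state$time,
              n_fired = state$n_fired, n_passivated = state$n_passivated,
              n_merges = state$n_merges, n_loaded = state$n_loaded,
              n_free_final = state$n_free, lost_halves = state$lost_halves)
  new_sphase_record(res, params, lay)
}
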