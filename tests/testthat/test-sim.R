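test_that("factor arrival times follow exponentially relaxed loading", {
  set.seed(1)
  expect_equal(sample_factor_arrivals(100, 0), rep(0, 100))
  expect_length(sample_factor_arrivals(0, 5), 0)
  a <- replicate(200, mean(sample_factor_arrivals(1000, 10)))
  expect_equal(mean(a), 10, tolerance = 0.01)
  # loaded fraction at t = tau is 1 - exp(-1)
  frac <- replicate(200, mean(sample_factor_arrivals(187, 3) <= 3))
  expect_equal(mean(frac), 1 - exp(-1), tolerance = 0.02)
  # deterministic mode tracks round(ndt * (1 - exp(-t/tau))) exactly
  d <- sample_factor_arrivals(187, 3, loading = "deterministic")
  for (t in c(1, 3, 7)) {
    expect_equal(sum(d <= t), round(187 * (1 - exp(-t / 3))))
  }
})

test_that("firing probability matches its closed form and bounds", {
  p <- firing_probability(6e-3, 0.01, 840)
  expect_equal(p, 1 - (1 - 6e-3 * 0.01)^840, tolerance = 1e-12)
  expect_equal(p, 0.0491524, tolerance = 1e-6)
  expect_identical(firing_probability(6e-3, 0.01, 0), 0)
  expect_identical(firing_probability(0, 0.01, 500), 0)
  # monotone non-decreasing in each argument
  expect_true(all(diff(firing_probability(6e-3, 0.01, c(1, 10, 100, 1000))) > 0))
  expect_lt(firing_probability(6e-3, 0.005, 840), p)
  expect_error(firing_probability(200, 0.01, 10),
               class = "replikin_param_error")
})

test_that("firing attempts fire distinct origins and update the pool", {
  p <- quiet_params(tiny_genome(), v = 0.5, kon = 5e-3, ndt = 3, tau_load = 0,
                    dt = 0.05)
  set.seed(2)
  st <- replication_state(p)
  st <- replikin:::apply_arrivals(st)
  expect_equal(st$n_free, 3L)
  st2 <- attempt_firings(st, p)
  fired <- sum(st2$ori_status == 1L)
  expect_equal(st2$n_free, 3L - fired)
  expect_equal(st2$bound_halves, 2L * fired)
  expect_length(st2$intervals$s, fired)
  expect_true(all(st2$intervals$s == st2$intervals$e))
  # no free factors: no-op
  st0 <- st; st0$n_free <- 0L
  expect_identical(attempt_firings(st0, p)$n_fired, 0L)
})

test_that("single-factor firing frequency matches the per-step probability", {
  g <- genome_spec(tibble::tibble(chrom = "c", length = 4000),
                   place_origins_periodic(3000, 0.28, chrom = "c"))
  p <- quiet_params(g, v = 0.6, kon = 6e-3, ndt = 1, tau_load = 0, dt = 0.01)
  set.seed(3)
  st <- replikin:::apply_arrivals(replication_state(p))
  hits <- vapply(seq_len(4000), function(i) {
    attempt_firings(st, p)$n_fired
  }, integer(1))
  expect_equal(mean(hits), firing_probability(6e-3, 0.01, 840),
               tolerance = 0.08)
})

test_that("fork propagation passivates, merges and discards as specified", {
  # two converging forks 1 kb apart merge and release one factor
  g <- genome_spec(tibble::tibble(chrom = "c", length = 20),
                   tibble::tibble(chrom = "c", position = c(9, 10),
                                  status = "Synthetic"))
  p <- quiet_params(g, v = 0.6, kon = 1e-3, ndt = 2, tau_load = 0, dt = 1)
  st <- replication_state(p)
  st$intervals <- list(s = c(9, 10), e = c(9, 10), la = c(TRUE, TRUE),
                       ra = c(TRUE, TRUE))
  st$ori_status <- c(1L, 1L)
  st$pot_idx <- integer(0)
  st$n_free <- 0L; st$bound_halves <- 4L; st$n_loaded <- 2L
  st2 <- advance_forks(st, p)
  expect_length(st2$intervals$s, 1)
  expect_equal(st2$n_free, 1L)
  expect_equal(st2$n_merges, 1L)
  expect_equal(st2$bound_halves, 2L)
  # replication never exceeds the union of swept intervals
  expect_equal(st2$intervals$e - st2$intervals$s, 1 + 2 * 0.6)

  # a left-moving fork at 0.2 kb is discarded at the chromosome start
  g2 <- one_origin_genome(L = 10, x0 = 0.2)
  p2 <- quiet_params(g2, v = 0.6, kon = 1e-3, ndt = 1, tau_load = 0, dt = 1)
  st <- replication_state(p2)
  st$intervals <- list(s = 0.2, e = 0.2, la = TRUE, ra = TRUE)
  st$ori_status <- 1L; st$pot_idx <- integer(0)
  st$bound_halves <- 2L; st$n_loaded <- 1L
  st2 <- advance_forks(st, p2)
  expect_equal(st2$intervals$s, 0)
  expect_false(st2$intervals$la)
  expect_equal(st2$lost_halves, 1L)

  # a right-moving fork sweeps over a potential origin: passivation
  g3 <- genome_spec(tibble::tibble(chrom = "c", length = 20),
                    tibble::tibble(chrom = "c", position = c(10, 10.5),
                                   status = "Synthetic"))
  p3 <- quiet_params(g3, v = 0.6, kon = 1e-3, ndt = 1, tau_load = 0, dt = 1)
  st <- replication_state(p3)
  st$intervals <- list(s = 10, e = 10, la = TRUE, ra = TRUE)
  st$ori_status <- c(1L, 0L); st$pot_idx <- 2L
  st$bound_halves <- 2L; st$n_loaded <- 1L
  st2 <- advance_forks(st, p3)
  expect_equal(st2$ori_status[2], 2L)
  expect_equal(st2$n_passivated, 1L)
})

test_that("a step on a completed or empty state only advances time", {
  p <- quiet_params(tiny_genome(), v = 0.5, kon = 5e-3, ndt = 0, tau_load = 0,
                    dt = 0.05)
  st <- replication_state(p)
  st2 <- sim_step(st, p)
  expect_equal(st2$time, 0.05)
  expect_equal(st2$n_fired, 0L)
  expect_identical(st2$intervals, st$intervals)
})

test_that("composing steps reproduces the full simulation exactly", {
  for (seed in c(11, 99)) {
    p <- quiet_params(tiny_genome(), v = 0.5, kon = 5e-3, ndt = 4,
                      tau_load = 2, dt = 0.05)
    a <- simulate_sphase(p, seed = seed)
    b <- simulate_sphase_reference(p, seed = seed)
    expect_equal(as.data.frame(a$kinetics), as.data.frame(b$kinetics))
    expect_equal(a$replication_time, b$replication_time)
    expect_equal(as.data.frame(a$origins), as.data.frame(b$origins))
    expect_equal(a$counters, b$counters)
  }
  # also on a multi-origin periodic genome with end recycling
  p <- quiet_params(genome_periodic(200, 0.2), v = 1, kon = 4e-3, ndt = 6,
                    tau_load = 1, dt = 0.02, recycle_at_ends = TRUE)
  a <- simulate_sphase(p, seed = 7)
  b <- simulate_sphase_reference(p, seed = 7)
  expect_equal(as.data.frame(a$kinetics), as.data.frame(b$kinetics))
})

test_that("factor and DNA conservation hold at every step", {
  p <- quiet_params(genome_periodic(120, 0.15), v = 0.8, kon = 8e-3, ndt = 5,
                    tau_load = 1, dt = 0.05)
  set.seed(12)
  st <- replication_state(p)
  L <- sum(p$genome$chromosomes$length)
  prev_unrep <- L
  while (l_unreplicated(st) > 1e-9) {
    st <- sim_step(st, p)
    # factor bookkeeping: free + halves/2 accounts for every loaded factor
    expect_equal(st$n_free + (st$bound_halves + st$lost_halves +
                                st$spare_halves) / 2,
                 st$n_loaded)
    expect_lte(st$n_loaded, p$ndt)
    # DNA: replicated + unreplicated = L, unreplicated non-increasing
    unrep <- l_unreplicated(st)
    expect_equal(replikin:::state_l_replicated(st) + unrep, L)
    expect_lte(unrep, prev_unrep + 1e-9)
    # replication speed bound: <= 2 * forks * v * dt per step
    nf <- sum(st$intervals$la) + sum(st$intervals$ra)
    expect_lte(prev_unrep - unrep,
               (nf + 2 * st$n_fired) * p$v * p$dt + 1e-9)
    prev_unrep <- unrep
  }
  expect_equal(st$n_fired + st$n_passivated, length(st$ori_pos))
})

test_that("one-origin system follows the geometric firing-delay law", {
  # oracle: with one origin and one factor (tau = 0), the firing step count
  # G is geometric with success probability p1 = kon*dt, the firing time is
  # (G-1)*dt, and completion is deterministic afterwards:
  # T = (G-1)*dt + max(ceil(x0/(v dt)), ceil((L-x0)/(v dt))) * dt
  L <- 10; x0 <- 3; v <- 0.5; kon <- 0.2; dt <- 0.1
  p1 <- firing_probability(kon, dt, 1)
  cover_steps <- max(ceiling(x0 / (v * dt)), ceiling((L - x0) / (v * dt)))
  p <- quiet_params(one_origin_genome(L, x0), v = v, kon = kon, ndt = 1,
                    tau_load = 0, dt = dt)
  set.seed(21)
  runs <- lapply(seq_len(4000), function(i) simulate_sphase(p))
  tfire <- vapply(runs, function(r) r$origins$event_time[1], 0)
  tend <- vapply(runs, function(r) r$replication_time, 0)
  # completion is exactly firing time + coverage time, run by run
  expect_equal(tend, tfire + cover_steps * dt, tolerance = 1e-9)
  # firing delay: geometric law (chi-square goodness of fit)
  g <- round(tfire / dt) + 1
  kmax <- 15
  obs <- tabulate(pmin(g, kmax), kmax)
  expected <- c(stats::dgeom(0:(kmax - 2), p1),
                stats::pgeom(kmax - 2, p1, lower.tail = FALSE)) * length(g)
  chi <- sum((obs - expected)^2 / expected)
  expect_lt(chi, stats::qchisq(0.999, df = kmax - 1))
  expect_equal(mean(g), 1 / p1, tolerance = 0.05)
})

test_that("saturating factors fire every origin with no passivation", {
  g <- genome_periodic(100, 0.1)
  p <- quiet_params(g, v = 0.6, kon = 5, ndt = 50, tau_load = 0, dt = 0.01)
  rec <- simulate_sphase(p, seed = 31)
  expect_equal(rec$counters$n_fired, 10)
  expect_equal(rec$counters$n_passivated, 0)
  expect_true(all(rec$origins$lifecycle == "fired"))
})

test_that("every completed run exhausts the origin lifecycle", {
  p <- red_params(L = 600)
  for (s in 1:3) {
    rec <- simulate_sphase(p, seed = s)
    expect_equal(rec$counters$n_fired + rec$counters$n_passivated,
                 nrow(p$genome$origins))
    expect_true(all(rec$origins$lifecycle %in% c("fired", "passivated")))
    expect_equal(min(rec$kinetics$l_unrep), 0, tolerance = 1)
  }
})

test_that("ensembles are deterministic given the master seed", {
  p <- quiet_params(genome_uniform(150, 0.2), v = 0.6, kon = 6e-3, ndt = 10,
                    tau_load = 3)
  e1 <- simulate_ensemble(p, 5, seed = 42)
  e2 <- simulate_ensemble(p, 5, seed = 42)
  expect_identical(e1$runs, e2$runs)
  expect_identical(e1$kinetics, e2$kinetics)
  e3 <- simulate_ensemble(p, 5, seed = 43)
  expect_false(identical(e1$runs$replication_time, e3$runs$replication_time))
})

test_that("poisson pool mode draws per-run factor counts of the right mean", {
  p <- quiet_params(genome_uniform(60, 0.1), v = 1, kon = 0.05, ndt = 143,
                    tau_load = 0, dt = 0.05, ndt_mode = "poisson")
  ens <- simulate_ensemble(p, 400, seed = 44)
  expect_equal(mean(ens$runs$ndt), 143, tolerance = 0.02)
  expect_gt(sd(ens$runs$ndt), 0)
})

test_that("uniform-resample genomes are re-positioned each run", {
  p <- quiet_params(genome_uniform(300, 0.1), v = 0.6, kon = 6e-3, ndt = 20,
                    tau_load = 0)
  ens <- simulate_ensemble(p, 3, seed = 45)
  expect_equal(unique(ens$runs$n_pori0), 30)
  # fired-origin times differ across runs (fresh positions + fresh kinetics)
  expect_gt(length(unique(vapply(ens$fired_times, sum, 0))), 1)
})

test_that("halving dt leaves ensemble kinetics unchanged within noise", {
  mk <- function(dtt, seed) {
    p <- quiet_params(genome_periodic(600, 0.28), v = 0.6, kon = 6e-3,
                      ndt = 33, tau_load = 3, dt = dtt)
    simulate_ensemble(p, 50, seed = seed)
  }
  ea <- mk(0.02, 61); eb <- mk(0.01, 62)
  ta <- replication_times(ea); tb <- replication_times(eb)
  se <- sqrt(var(ta) / length(ta) + var(tb) / length(tb))
  expect_lt(abs(mean(ta) - mean(tb)), 2 * se + 0.05 * mean(ta) * 0)
  ia <- estimate_imax(ensemble_kinetics(ea, 1))
  ib <- estimate_imax(ensemble_kinetics(eb, 1))
  expect_lt(abs(ia$imax - ib$imax), 2 * sqrt(ia$i_se^2 + ib$i_se^2) +
              0.1 * ia$imax)
})

test_that("zero factors cannot finish and trip the guard", {
  p <- quiet_params(one_origin_genome(), v = 1, kon = 0.01, ndt = 0,
                    tau_load = 0, dt = 0.1, max_time = 10)
  expect_error(simulate_sphase(p, seed = 1), regexp = "max_time")
})
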