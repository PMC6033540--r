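---
title: "Modeling the temporal program of DNA replication origin firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the temporal program of DNA replication origin firing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Eukaryotic genomes replicate from many chromosomal loci, the *potential
origins* (p-oris), licensed before S-phase. During S-phase a limiting pool of
diffusing *firing factors* activates origins: a productive encounter between
a free factor and a p-ori fires the origin, creating two divergent
replication forks. The factor splits into two halves that travel with the
forks; when two converging forks merge (termination) the factor reforms and
returns to the free pool. A fork that passes over an unfired p-ori
*passivates* it. The central observable is the firing rate per length of
unreplicated DNA,

$$ I_S(t) \;=\; \frac{N_\mathrm{fired}(t, t+\mathrm{d}t)}
                    {L_\mathrm{unrep}(t)\,\mathrm{d}t}, $$

which across eukaryotes has a universal bell shape: a rise past mid-S-phase
followed by a decay to zero.

`replikin` implements the well-mixed version of this picture as a
fixed-time-step stochastic event loop. Per step of length `dt`, in order:

1. **Loading.** Factors become available at exponentially distributed times
   of mean `tau_load` ("exponentially relaxed loading"); after loading the
   total pool `ndt` is constant. A deterministic-count loading mode exists
   for variance-reduction experiments.
2. **Firing.** Each of the $N_{FD}(t)$ free factors independently fires with
   probability $1 - (1 - k_{on}\,\mathrm{d}t)^{N_\mathrm{p\text{-}ori}(t)}$,
   with the potential-origin count frozen at step start (within-step
   depletion is second order in `dt`). Every success activates a distinct
   uniformly chosen potential origin and spawns two forks; surplus successes
   beyond the available origins are no-ops.
3. **Propagation.** Every fork moves `v * dt`; newly replicated DNA
   passivates the potential origins it covers; converging forks merge,
   each merger returning one factor to the free pool; forks reaching a
   chromosome end are discarded.

The loop ends when no unreplicated DNA remains; that time is the S-phase
duration of the run.

### Closed-form layer

With a bimolecular firing rate $I(t) = k_{on} N_{FD}(t) \rho(t)$
($\rho$ = p-ori density over unreplicated DNA), the fate of $\rho$ is a
competition between the time to fire an origin, $t_c = 1/(k_{on} N_{FD})$,
and the time for a fork to cover the distance $d$ between neighbouring
unreplicated origins, $t_r = d/v$. Density holds steady while
$N_{FD} < N_{FD}^* = v/(k_{on} d)$ and collapses beyond, giving the predicted
ceiling

$$ I_\mathrm{max} \;=\; k_{on}\,\rho_0\,N_{FD}^* \;\approx\; v\,\rho_0^2
\qquad (d \approx 1/\rho_0). $$

`critical_free_factors()`, `bimolecular_rate()`, `density_criterion()`,
`predicted_imax()` and `two_compartment_imax()` (the factor-½ bound for a
genome split into early/late compartments) expose these forms;
`rescale_parameters()` applies the invariance
$L \to \alpha L,\; N_{DT} \to \alpha N_{DT},\; k_{on} \to k_{on}/\alpha$,
which preserves $I(t)$ and $\rho_0$ and lets huge genomes be simulated at
tractable lengths.

## Parameters

| name | meaning | units | default |
|---|---|---|---|
| `v` | fork speed | kb/min | required |
| `kon` | productive-interaction rate | min⁻¹ | required |
| `ndt` | total firing factors | count | required |
| `tau_load` | loading timescale | min | 0 |
| `dt` | time step | min | 0.01 |
| `rho0` | initial p-ori density | kb⁻¹ | from genome |
| `ndt_mode` | `constant` / `poisson` pool | — | constant |
| `recycle_at_ends` | re-pair end-discarded half factors | — | `FALSE` |

`dt = 0.01` min is small enough that halving it changes ensemble means by
less than Monte-Carlo noise (a property the test suite checks); the firing
probability requires `kon * dt <= 1`, and a warning is raised when `v * dt`
exceeds half the smallest inter-origin gap. All coordinates are continuous
(kb), 0-based, half-open per chromosome — no lattice, hence no
discretization artifacts in fork positions.

## Genomes and the synthetic-data generator

Three genome sources mirror the two biological settings:

* `genome_uniform(length, rho0)` — embryo-style: `round(L * rho0)` origins
  i.i.d. uniform, **re-drawn for every simulated S-phase** (each cell cycle
  sees fresh positions). Duplicate draws are redrawn (a measure-zero event);
  this keeps the origin count exact.
* `genome_periodic(length, rho0)` — exactly one origin uniformly inside each
  non-overlapping `1/rho0` segment; a trailing partial segment carries no
  origin, keeping the spacing law exact.
* `read_origin_map()` — fixed maps from tab-separated files (chromosome,
  start, end, name, status ∈ Confirmed/Likely/Dubious), OriDB-style.
  Interval records collapse to their midpoint (the unbiased point choice;
  `collapse = "start"` is available since databases do not state which
  convention downstream users want).

`synthetic_origin_map()` is the generator used by the tests: it emulates a
curated database export — per-status origin counts, multi-chromosome,
either uniform placement or `"even"` placement (largest-remainder
apportionment across chromosomes, one origin per equal segment). The bundled
`extdata/yeast_synthetic_origins.tsv` uses even placement over the 16
budding-yeast chromosome lengths with 410/216/203
Confirmed/Likely/Dubious origins, because the real yeast origin map is well
positioned: under uniform placement the largest random origin gap and the
bare chromosome ends dominate the completion time (we measure ~18 min extra
mean S-phase and doubled spread), which misrepresents a map whose origins
are evenly spread. What the generator does **not** emulate: sequence
context, origin-strength heterogeneity, the rDNA locus, centromere/telomere
effects; passing tests therefore speak to the kinetic mechanism, not to
locus-level replication timing of the real genome.

## Estimators and numerical choices

* **Pooled I(t)** is a ratio of sums across runs per time bin,
  $\sum \mathrm{fired} / \sum L_\mathrm{unrep}\mathrm{d}t$, never a mean of
  per-run ratios — the latter blows up as individual runs exhaust their
  unreplicated DNA. Standard errors come from a seeded run-level bootstrap
  (200 resamples by default); the caller's RNG state is restored.
* **Default bins**: 0.5 min for embryo-scale runs, 1 min for yeast-scale.
* **Imax** is the maximum of pooled I(t) over bins whose ensemble-mean
  unreplicated fraction exceeds `tail_exclusion` (default 5%), so the
  estimate is not dominated by end-of-S small-denominator noise.
* **Passivation/activation ratio**: per-bin passivated over fired counts;
  bins without activations are `NA` (undefined), never zero.
* **Fork mergers** cap replication at the midpoint of the gap remaining at
  step start; a fork created in a step can merge within that same step.
* **End-discarded forks** lose their half factor by default: termination is
  the only documented factor-release event, and crediting chromosome ends
  would inflate the late free pool. `recycle_at_ends = TRUE` restores the
  halves in pairs for sensitivity analysis; on the genome scales shipped
  here the difference is a handful of halves per run.
* **Within-step order** (arrivals → firings → propagation) is a convention;
  the alternatives differ at $O(\mathrm{d}t)$ and vanish under the
  `dt`-halving check.
* **Reproducibility**: `simulate_ensemble(..., seed = s)` derives per-run
  seeds with one `sample.int()` draw under `set.seed(s)`; the manifest
  written by `write_results()` pins parameters, seed and version, and
  regenerating from the manifest is bit-identical.

The compiled event loop consumes R's RNG in a fixed draw order, and the
package carries a plain-R step-level implementation
(`replication_state()`, `attempt_firings()`, `advance_forks()`,
`sim_step()`) that reproduces the compiled trajectories *exactly*, seed for
seed — the per-step semantics are therefore testable in isolation and the
production path is cross-validated against them.

## What the model reproduces, and where its shape is subtle

With strong interaction and a limiting pool
(`kon = 6e-3`, `ndt = 165`, periodic `rho0 = 0.28` on 3000 kb, the standard
strong-firing reference set), the pooled I(t) is bell-shaped: flat and low
while passivation outpaces activation, rising as fork mergers free factors,
and collapsing to zero as the origin pool empties. Weak interaction
(`kon = 5e-5`, `ndt = 1000`) yields a slow monotone rise; moderate
interaction (`kon = 6e-4`, `ndt = 250`) a pronounced rise toward the
pool-limited plateau. The embryo-style uniform ensemble (`rho0 = 0.70`,
`ndt = 187`, `kon = 3e-3`) activates ≈ 0.16–0.17 origins per kb, and the
yeast-scale synthetic map gives a tight S-phase duration distribution whose
spread widens — without derailing — under Poisson cell-to-cell variability
of the factor pool.

Two quantitative subtleties, established by the test suite and worth knowing
before comparing to the closed forms:

* The pooled I(t) keeps rising for a few minutes *after* the free pool
  crosses $N_{FD}^*$ and the passivation/activation ratio drops below one:
  the density collapse and the free-pool growth compete, and with the 5%
  tail-exclusion estimator the measured maximum lands above $v\rho_0^2$
  (about 1.5× for the strong-firing reference set) and later than the
  balance tipping point. The coincidence of the three markers is exact only
  in the idealized closed-form argument.
* Across a >10-fold density sweep the measured Imax follows the
  $v\rho_0^2$ diagonal as an order-of-magnitude law (all points within a
  factor ~2), tight near the middle of each family's valid regime and
  loosening toward its edges — at one edge the pool stops being limiting, at
  the other S-phase ends before the free pool can reach $N_{FD}^*$.
* The rescaling transformation preserves pooled I(t) (indistinguishable
  within bootstrap error) but the completion time is an extreme-value
  statistic: doubling the genome shifts mean S-phase duration by a fraction
  of a minute, right at the edge of detectability of our 60-run ensembles.

## Problem sizes

The shipped tests use one 3000-kb chromosome for embryo-style ensembles
(30–100 runs), the 12.1-Mb synthetic yeast map (40–60 runs), density sweeps
at 30–40 runs per point, and step-level checks on 10–600 kb toy genomes;
the whole suite completes in a few minutes on one core. Larger ensembles
only tighten the Monte-Carlo error around the same values.

## Limitations

Space enters only through origin positions on 1D chromosomes: no 3D
diffusion of factors, no chromatin context, no checkpoint signalling beyond
a joint `(v, kon)` rescaling, no origin-to-origin strength differences. The
package emits aggregate kinetics (plus per-origin event times for future
use), not replication-timing profiles along coordinates.
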