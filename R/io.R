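# Flat-YAML run configuration and result serialization.
#
# Schema (flat keys, fixed units kb/min). Required: genome_source
# (uniform | periodic | file), v, kon, ndt. Genome keys: length_kb + rho0
# (uniform/periodic) or origin_file + categories (file). Optional with
# defaults: tau_load (0), dt (0.01), ndt_mode (constant), recycle_at_ends
# (false), loading (stochastic), n_runs (100), bin_width (0.5), seed (1),
# collapse (midpoint), max_time (1e5).

config_keys <- function() {
  list(required = c("genome_source", "v", "kon", "ndt"),
       optional = c("length_kb", "rho0", "origin_file", "categories",
                    "tau_load", "dt", "ndt_mode", "recycle_at_ends",
                    "loading", "n_runs", "bin_width", "seed", "collapse",
                    "max_time"))
}

#' Load a run configuration
#'
#' Reads a flat YAML configuration (documented schema in the package
#' vignette; units fixed at kb and min), validates keys and returns a
#' `run_config` list. Unknown keys and missing required keys raise errors
#' naming the offending keys.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ks <- config_keys()
  unknown <- setdiff(names(cfg), c(ks$required, ks$optional))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "replikin_config_error")
  }
  missing <- setdiff(ks$required, names(cfg))
  if (length(missing)) {
    abort(paste0("missing required config key(s): ",
                 paste(missing, collapse = ", ")),
          class = "replikin_config_error")
  }
  defaults <- list(tau_load = 0, dt = 0.01, ndt_mode = "constant",
                   recycle_at_ends = FALSE, loading = "stochastic",
                   n_runs = 100L, bin_width = 0.5, seed = 1L,
                   collapse = "midpoint", max_time = 1e5)
  cfg <- utils::modifyList(defaults, cfg)
  src <- cfg$genome_source
  if (!src %in% c("uniform", "periodic", "file")) {
    abort("genome_source must be uniform, periodic or file",
          class = "replikin_config_error")
  }
  need <- if (src == "file") "origin_file" else c("length_kb", "rho0")
  miss2 <- setdiff(need, names(cfg))
  if (length(miss2)) {
    abort(paste0("missing config key(s) for genome_source=", src, ": ",
                 paste(miss2, collapse = ", ")),
          class = "replikin_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Build simulation parameters from a run configuration
#'
#' @param config A `run_config` from [load_run_config()].
#' @param base_dir Directory against which a relative `origin_file` is
#'   resolved (defaults to the working directory).
#' @return A [sim_params()].
#' @export
as_sim_params <- function(config, base_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  genome <- switch(config$genome_source,
    uniform = genome_uniform(config$length_kb, config$rho0),
    periodic = genome_periodic(config$length_kb, config$rho0),
    file = read_origin_map(
      if (file.exists(config$origin_file)) config$origin_file
      else file.path(base_dir, config$origin_file),
      categories = config$categories %||% c("Confirmed", "Likely", "Dubious"),
      collapse = config$collapse))
  sim_params(genome, v = config$v, kon = config$kon, ndt = config$ndt,
             tau_load = config$tau_load, dt = config$dt,
             ndt_mode = config$ndt_mode,
             recycle_at_ends = isTRUE(config$recycle_at_ends),
             loading = config$loading, max_time = config$max_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ensemble results to a directory
#'
#' Emits the pooled kinetics table (`kinetics.tsv`, tab-separated with a
#' parameter-echo comment header), the per-run summary (`runs.tsv`), the
#' replication-time samples (`replication_times.txt`, one value per line,
#' minutes), the firing-event log (`firing_events.tsv`: run, firing time)
#' and a machine-readable JSON manifest (`manifest.json`) carrying
#' every parameter, the master seed and the package version — enough to
#' regenerate the outputs bit for bit.
#'
#' @param ensemble A `replication_ensemble`.
#' @param dir Output directory (created if needed).
#' @param bin_width Bin width for the pooled kinetics table (min).
#' @param seed The master seed used to produce `ensemble` (stored in the
#'   manifest).
#' @return `dir`, invisibly.
#' @export
write_results <- function(ensemble, dir, bin_width = 0.5, seed = NULL) {
  stopifnot(inherits(ensemble, "replication_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- ensemble$params
  ek <- ensemble_kinetics(ensemble, bin_width)
  hdr <- sprintf(
    "# replikin kinetics; v=%g kb/min kon=%g /min NDT=%d tau=%g min dt=%g min L=%g kb n_runs=%d bin=%g min",
    p$v, p$kon, p$ndt, p$tau_load, p$dt, ensemble$genome_length,
    ensemble$n_runs, bin_width)
  f <- file.path(dir, "kinetics.tsv")
  writeLines(hdr, f)
  suppressWarnings(utils::write.table(
    as.data.frame(ek), f, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  utils::write.table(as.data.frame(ensemble$runs),
                     file.path(dir, "runs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(format(replication_times(ensemble), trim = TRUE),
             file.path(dir, "replication_times.txt"))
  ft <- tibble(run = rep(seq_along(ensemble$fired_times),
                         lengths(ensemble$fired_times)),
               t_fired = unlist(ensemble$fired_times, use.names = FALSE))
  utils::write.table(as.data.frame(ft), file.path(dir, "firing_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- p$genome
  manifest <- list(
    package = "replikin",
    version = as.character(utils::packageVersion("replikin")),
    seed = seed, n_runs = ensemble$n_runs, bin_width = bin_width,
    params = list(v = p$v, kon = p$kon, ndt = p$ndt, tau_load = p$tau_load,
                  dt = p$dt, ndt_mode = p$ndt_mode,
                  recycle_at_ends = p$recycle_at_ends, loading = p$loading),
    genome = list(resample = g$resample, rho0 = g$rho0,
                  n_origins = nrow(g$origins),
                  categories = sort(unique(g$origins$status)),
                  length_kb = sum(g$chromosomes$length),
                  n_chromosomes = nrow(g$chromosomes)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read back a kinetics table written by [write_results()]
#' @param path Path to `kinetics.tsv`.
#' @return A tibble.
#' @export
read_kinetics_table <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              comment.char = "#"))
}
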