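# small genomes and parameter sets shared across test files

tiny_genome <- function() {
  genome_spec(
    tibble::tibble(chrom = c("a", "b"), length = c(60, 40)),
    tibble::tibble(chrom = c("a", "a", "a", "b", "b"),
                   position = c(5, 22, 47, 10, 33),
                   status = "Synthetic"))
}

one_origin_genome <- function(L = 10, x0 = 3) {
  genome_spec(tibble::tibble(chrom = "chr1", length = L),
              tibble::tibble(chrom = "chr1", position = x0,
                             status = "Synthetic"))
}

quiet_params <- function(...) suppressWarnings(sim_params(...))

# strong-interaction set (bell-shaped I(t)): periodic origins
red_params <- function(L = 3000)
  quiet_params(genome_periodic(L, 0.28), v = 0.6, kon = 6e-3, ndt = 165,
               tau_load = 3)

# synthetic stand-in for the budding-yeast origin map: real chromosome
# lengths, 829 origins (410/216/203), evenly placed
yeast_standin <- function(seed = 20) {
  set.seed(seed)
  synthetic_origin_map(yeast_chromosome_lengths(),
                       c(Confirmed = 410, Likely = 216, Dubious = 203),
                       placement = "even")
}
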