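#' Construct a genome specification
#'
#' A `genome_spec` bundles an ordered set of chromosomes with a map of
#' potential replication origins (p-oris) and the derived origin density
#' `rho0 = N_pori / L`. Coordinates are continuous, in kb, 0-based and
#' half-open: positions live in `[0, length)` per chromosome.
#'
#' @param chromosomes A data frame with columns `chrom` (character) and
#'   `length` (kb, positive).
#' @param origins A data frame with columns `chrom`, `position` (kb) and
#'   `status` (one of `"Confirmed"`, `"Likely"`, `"Dubious"`, `"Synthetic"`).
#' @param resample One of `"none"`, `"uniform"`, `"periodic"`. For embryo-like
#'   genomes where each S-phase sees a fresh random origin positioning,
#'   ensembles re-draw positions per run with the stated scheme at the
#'   genome's `rho0`; `"none"` keeps positions fixed (yeast-like maps).
#'
#' @return An object of class `genome_spec`: a list with elements
#'   `chromosomes` (tibble), `origins` (tibble, sorted by chromosome then
#'   position), `rho0` (kb^-1) and `resample`.
#' @examples
#' gs <- genome_spec(
#'   tibble::tibble(chrom = "chr1", length = 100),
#'   tibble::tibble(chrom = "chr1", position = c(10, 55), status = "Synthetic")
#' )
#' gs$rho0
#' @export
genome_spec <- function(chromosomes, origins, resample = "none") {
  chromosomes <- as_tibble(chromosomes)
  origins <- as_tibble(origins)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            all(c("chrom", "position") %in% names(origins)))
  if (!"status" %in% names(origins)) origins$status <- "Synthetic"
  if (any(chromosomes$length <= 0)) {
    abort("chromosome lengths must be positive", class = "replikin_param_error")
  }
  resample <- match.arg(resample, c("none", "uniform", "periodic"))
  bad <- !origins$status %in% c("Confirmed", "Likely", "Dubious", "Synthetic")
  if (any(bad)) {
    abort(paste0("unknown origin status: ",
                 paste(unique(origins$status[bad]), collapse = ", ")),
          class = "replikin_param_error")
  }
  if (nrow(origins) > 0) {
    len <- setNames(chromosomes$length, chromosomes$chrom)
    if (!all(origins$chrom %in% chromosomes$chrom)) {
      abort("origin on unknown chromosome", class = "replikin_validation_error")
    }
    out <- origins$position < 0 | origins$position >= len[origins$chrom]
    if (any(out)) {
      abort(sprintf("%d origin(s) outside chromosome bounds", sum(out)),
            class = "replikin_validation_error")
    }
    origins <- dplyr::arrange(origins, match(.data$chrom, chromosomes$chrom),
                              .data$position)
    dup <- duplicated(origins[c("chrom", "position")])
    if (any(dup)) {
      abort("duplicate origin positions", class = "replikin_validation_error")
    }
  }
  L <- sum(chromosomes$length)
  structure(
    list(chromosomes = chromosomes,
         origins = origins[c("chrom", "position", "status")],
         rho0 = nrow(origins) / L,
         resample = resample),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_spec> %d chromosome(s), L = %.1f kb, %d p-oris, rho0 = %.4g kb^-1\n",
    nrow(x$chromosomes), sum(x$chromosomes$length), nrow(x$origins), x$rho0))
  invisible(x)
}

#' Random placement of potential origins
#'
#' `place_origins_uniform()` draws `round(length * rho0)` origin positions
#' i.i.d. uniform on `[0, length)` (duplicates redrawn).
#' `place_origins_periodic()` places exactly one origin uniformly within each
#' consecutive non-overlapping segment of length `1/rho0`; a trailing partial
#' segment carries no origin, so the count is `floor(length * rho0)`.
#'
#' @param length Chromosome length in kb.
#' @param rho0 Target origin density in kb^-1.
#' @param chrom Chromosome label for the returned map.
#' @return A tibble with columns `chrom`, `position`, `status` (`"Synthetic"`),
#'   sorted by position.
#' @examples
#' set.seed(1)
#' nrow(place_origins_uniform(3000, 0.28))
#' nrow(place_origins_periodic(3000, 0.28))
#' @export
place_origins_uniform <- function(length, rho0, chrom = "chr1") {
  if (length <= 0 || rho0 < 0) {
    abort("length must be > 0 and rho0 >= 0", class = "replikin_param_error")
  }
  n <- round(length * rho0)
  pos <- runif(n, 0, length)
  while (anyDuplicated(pos)) {          # measure-zero; keeps count exact
    i <- which(duplicated(pos))
    pos[i] <- runif(length(i), 0, length)
  }
  tibble(chrom = chrom, position = sort(pos), status = "Synthetic")
}

#' @rdname place_origins_uniform
#' @export
place_origins_periodic <- function(length, rho0, chrom = "chr1") {
  if (length <= 0 || rho0 <= 0 || length < 1 / rho0) {
    abort("need length >= 1/rho0 > 0 for periodic placement",
          class = "replikin_param_error")
  }
  n <- floor(length * rho0)
  seg <- 1 / rho0
  pos <- (seq_len(n) - 1) * seg + runif(n, 0, seg)
  tibble(chrom = chrom, position = pos, status = "Synthetic")
}

#' Single-chromosome genomes with randomly placed origins
#'
#' Convenience constructors for embryo-style genomes: one chromosome of the
#' given length with origins placed uniformly or periodically at density
#' `rho0`. The returned spec carries `resample` set accordingly, so ensembles
#' re-position origins independently for every simulated S-phase.
#'
#' @inheritParams place_origins_uniform
#' @return A [genome_spec()].
#' @export
genome_uniform <- function(length, rho0) {
  genome_spec(tibble(chrom = "chr1", length = length),
              place_origins_uniform(length, rho0),
              resample = "uniform")
}

#' @rdname genome_uniform
#' @export
genome_periodic <- function(length, rho0) {
  genome_spec(tibble(chrom = "chr1", length = length),
              place_origins_periodic(length, rho0),
              resample = "periodic")
}

#' Read an origin map file
#'
#' Reads a tab-separated origin map in an OriDB-style dialect: optional
#' comment lines starting `#`, optional header records
#' `#chrom <name> <length_kb>`, then data columns
#' `chrom  start_kb  end_kb  name  status` with status in
#' Confirmed | Likely | Dubious (BED3+2-compatible ordering, kb units).
#' Each origin interval is collapsed to a point, by default its midpoint.
#' Chromosome lengths come from the header records or, absent those, from the
#' maximum end coordinate per chromosome.
#'
#' @param path File path.
#' @param categories Character vector of status categories to keep.
#' @param collapse `"midpoint"` (default) or `"start"`: how an interval
#'   becomes a point position.
#' @return A [genome_spec()] containing only the selected categories.
#' @export
read_origin_map <- function(path,
                            categories = c("Confirmed", "Likely", "Dubious"),
                            collapse = c("midpoint", "start")) {
  collapse <- match.arg(collapse)
  if (length(categories) == 0) {
    abort("categories must be nonempty", class = "replikin_param_error")
  }
  lines <- readLines(path)
  hdr <- grepl("^#chrom\\s", lines)
  chrom_tbl <- NULL
  if (any(hdr)) {
    parts <- strsplit(trimws(sub("^#chrom\\s+", "", lines[hdr])), "\\s+")
    chrom_tbl <- tibble(
      chrom = vapply(parts, `[`, "", 1),
      length = as.numeric(vapply(parts, `[`, "", 2)))
  }
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  rows <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5 || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) {
      abort(sprintf("malformed origin record at line %d of %s", i, path),
            class = "replikin_parse_error")
    }
    rows[[k]] <- tibble(chrom = f[1], start = as.numeric(f[2]),
                        end = as.numeric(f[3]), name = f[4], status = f[5])
  }
  dat <- dplyr::bind_rows(rows)
  if (nrow(dat) == 0) {
    dat <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), status = character())
  }
  if (is.null(chrom_tbl)) {
    chrom_tbl <- dplyr::summarise(dplyr::group_by(dat, .data$chrom),
                                  length = max(.data$end), .groups = "drop")
  }
  dat <- dat[dat$status %in% categories, , drop = FALSE]
  pos <- if (collapse == "midpoint") (dat$start + dat$end) / 2 else dat$start
  # a point collapsed exactly onto the chromosome end is nudged inside [0, L)
  len <- setNames(chrom_tbl$length, chrom_tbl$chrom)
  if (nrow(dat) > 0) pos <- pmin(pos, len[dat$chrom] - 1e-9)
  genome_spec(chrom_tbl,
              tibble(chrom = dat$chrom, position = unname(pos),
                     status = dat$status))
}

#' Write an origin map file
#'
#' Serializes a [genome_spec()] (or an origin tibble plus chromosome table)
#' in the dialect read by [read_origin_map()]. Point origins are written as
#' zero-width-collapsed intervals `[position - w/2, position + w/2]` so that
#' midpoint collapse round-trips exactly; `w = 0` by default.
#'
#' @param genome A [genome_spec()].
#' @param path Output file path.
#' @param interval_width Width in kb of the written interval around each
#'   origin position (clipped to the chromosome).
#' @return `path`, invisibly.
#' @export
write_origin_map <- function(genome, path, interval_width = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# origin map (tab-separated; kb); status: Confirmed|Likely|Dubious",
             con)
  for (i in seq_len(nrow(genome$chromosomes))) {
    writeLines(sprintf("#chrom %s %.3f", genome$chromosomes$chrom[i],
                       genome$chromosomes$length[i]), con)
  }
  o <- genome$origins
  if (nrow(o) > 0) {
    len <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    s <- pmax(o$position - interval_width / 2, 0)
    e <- pmin(o$position + interval_width / 2, len[o$chrom])
    writeLines(sprintf("%s\t%.3f\t%.3f\tori_%d\t%s",
                       o$chrom, s, e, seq_len(nrow(o)), o$status), con)
  }
  invisible(path)
}

#' Generate a synthetic OriDB-like origin map
#'
#' Builds a random multi-chromosome origin map with given per-status counts.
#' With `placement = "uniform"` origins fall i.i.d. uniform, allocated to
#' chromosomes proportionally to length; with `placement = "even"` the
#' origin count per chromosome follows largest-remainder apportionment and
#' each chromosome receives one origin uniformly within each of its equal
#' segments, emulating the well-positioned, regularly spread origin maps of
#' organisms like budding yeast. Status labels are randomly permuted across
#' origins. Useful as a self-contained stand-in for a database export in
#' tests and examples.
#'
#' @param lengths Numeric vector of chromosome lengths (kb); names become
#'   chromosome ids (default `chr1..chrN`).
#' @param counts Named integer vector/list of origin counts per status, e.g.
#'   `c(Confirmed = 410, Likely = 216, Dubious = 203)`.
#' @param placement `"uniform"` or `"even"` (see above).
#' @return A [genome_spec()] with `resample = "none"`.
#' @export
synthetic_origin_map <- function(lengths, counts,
                                 placement = c("uniform", "even")) {
  placement <- match.arg(placement)
  if (any(lengths <= 0)) {
    abort("lengths must be positive", class = "replikin_param_error")
  }
  ids <- names(lengths)
  if (is.null(ids)) ids <- paste0("chr", seq_along(lengths))
  counts <- unlist(counts)
  n <- sum(counts)
  chrom_tbl <- tibble(chrom = ids, length = unname(lengths))
  if (n == 0) {
    return(genome_spec(chrom_tbl,
                       tibble(chrom = character(), position = numeric(),
                              status = character())))
  }
  len <- setNames(unname(lengths), ids)
  if (placement == "uniform") {
    chrom <- sample(ids, n, replace = TRUE, prob = lengths / sum(lengths))
    pos <- runif(n, 0, len[chrom])
    while (anyDuplicated(paste(chrom, pos))) {
      i <- which(duplicated(paste(chrom, pos)))
      pos[i] <- runif(length(i), 0, len[chrom[i]])
    }
  } else {
    # largest-remainder apportionment of n origins over chromosomes
    share <- n * len / sum(len)
    k <- floor(share)
    rem <- n - sum(k)
    if (rem > 0) {
      extra <- order(share - k, decreasing = TRUE)[seq_len(rem)]
      k[extra] <- k[extra] + 1
    }
    chrom <- rep(ids, k)
    pos <- unlist(lapply(ids, function(cn) {
      if (k[cn] == 0) return(numeric(0))
      seg <- len[cn] / k[cn]
      (seq_len(k[cn]) - 1) * seg + runif(k[cn], 0, seg)
    }), use.names = FALSE)
  }
  status <- sample(rep(names(counts), counts))
  genome_spec(chrom_tbl, tibble(chrom = chrom, position = pos,
                                status = status))
}

#' S. cerevisiae-like chromosome lengths
#'
#' The 16 budding-yeast chromosome lengths in kb (rounded to the nearest kb),
#' totalling about 12.1 Mb. Used to build synthetic yeast-scale genomes.
#'
#' @return A named numeric vector of 16 lengths (kb).
#' @export
yeast_chromosome_lengths <- function() {
  c(chr1 = 230, chr2 = 813, chr3 = 317, chr4 = 1532, chr5 = 577,
    chr6 = 270, chr7 = 1091, chr8 = 563, chr9 = 440, chr10 = 745,
    chr11 = 667, chr12 = 1078, chr13 = 924, chr14 = 784, chr15 = 1091,
    chr16 = 948)
}
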