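#' Demographic scenario for the serial-coalescent generator
#'
#' A single-population, piecewise-constant demography. Epoch start
#' times are in generations before present, so the first epoch (start
#' 0) is the most recent one and sizes further down the list apply
#' deeper in the past.
#'
#' @param id Short scenario name.
#' @param epochs data.frame with columns `start_time` (generations
#'   before present, strictly increasing from 0) and `ne` (diploid
#'   effective size, > 0).
#' @param description Free-text description.
#' @return An object of class `demography_scenario`.
#' @export
demography_scenario <- function(id, epochs, description = "") {
  stopifnot(is.data.frame(epochs),
            all(c("start_time", "ne") %in% names(epochs)),
            nrow(epochs) >= 1)
  if (epochs$start_time[1] != 0) stop("first epoch must start at time 0")
  if (any(diff(epochs$start_time) <= 0)) {
    stop("epoch start times must be strictly increasing")
  }
  if (any(epochs$ne <= 0)) stop("all Ne must be positive")
  structure(list(id = id, epochs = epochs, description = description),
            class = "demography_scenario")
}

#' @export
print.demography_scenario <- function(x, ...) {
  cat("demography_scenario <", x$id, ">: ", x$description, "\n", sep = "")
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

#' Default library of validation demographies
#'
#' Ten single-population scenarios spanning constant size, population
#' contractions and expansions of several magnitudes and onset times,
#' with and without recovery, against a common baseline size. They are
#' the demographic conditions under which clock recovery is exercised.
#'
#' @param base_ne Baseline diploid effective size (default 1000).
#' @return Named list of [demography_scenario()] objects.
#' @export
scenario_library <- function(base_ne = 1000) {
  ep <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start_time = m[, 1], ne = m[, 2])
  }
  scn <- list(
    demography_scenario("constant", ep(0, base_ne),
                        "constant population size"),
    demography_scenario("contract5_200",
                        ep(0, base_ne / 5, 200, base_ne),
                        "5-fold contraction 200 generations ago"),
    demography_scenario("contract10_200",
                        ep(0, base_ne / 10, 200, base_ne),
                        "10-fold contraction 200 generations ago"),
    demography_scenario("contract50_200",
                        ep(0, base_ne / 50, 200, base_ne),
                        "50-fold contraction 200 generations ago"),
    demography_scenario("contract5_500",
                        ep(0, base_ne / 5, 500, base_ne),
                        "5-fold contraction 500 generations ago"),
    demography_scenario("contract10_500",
                        ep(0, base_ne / 10, 500, base_ne),
                        "10-fold contraction 500 generations ago"),
    demography_scenario("expand5_200",
                        ep(0, base_ne * 5, 200, base_ne),
                        "5-fold expansion 200 generations ago"),
    demography_scenario("expand10_200",
                        ep(0, base_ne * 10, 200, base_ne),
                        "10-fold expansion 200 generations ago"),
    demography_scenario("contract_recover",
                        ep(0, base_ne, 100, base_ne / 10, 500, base_ne),
                        "10-fold contraction 500-100 generations ago, recovered"),
    demography_scenario("expand_recover",
                        ep(0, base_ne, 100, base_ne * 10, 500, base_ne),
                        "10-fold expansion 500-100 generations ago, reverted")
  )
  stats::setNames(scn, vapply(scn, `[[`, "", "id"))
}

#' Design of a serial-sampling simulation
#'
#' Defaults are desk-scale: 4 chromosomes of 10 Mb, the transversion
#' mutation rate 2.3e-8 and recombination rate 1e-8 per bp per
#' generation, and 20 haploid lineages sampled every 100 generations
#' from 900 generations ago to the present, the most recent cohort
#' being self-paired. The full-scale validation layout (31 chromosomes
#' of 75 Mb) is available by argument.
#'
#' @param n_chromosomes Number of independently simulated chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param recomb_rate Recombination rate per bp per generation.
#' @param mut_rate Mutation rate per bp per generation.
#' @param sample_times Sampling times in generations before present,
#'   ascending, starting at 0.
#' @param haploids_per_time Haploid lineages sampled at each time (even
#'   when random pairing is used).
#' @param self_pair_most_recent Self-pair the most recent cohort
#'   (mimicking inbred modern genomes) instead of random pairing.
#' @param seed Master seed; chromosome, pairing and pseudo-haploid
#'   draws use seeds derived from it.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_chromosomes = 4, chrom_length = 1e7,
                              recomb_rate = 1e-8, mut_rate = 2.3e-8,
                              sample_times = seq(0, 900, by = 100),
                              haploids_per_time = 20,
                              self_pair_most_recent = TRUE,
                              seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0,
            recomb_rate > 0, mut_rate > 0,
            all(sample_times >= 0), !is.unsorted(sample_times),
            haploids_per_time >= 1)
  if (haploids_per_time %% 2 != 0) {
    stop("haploids_per_time must be even for random pairing")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = chrom_length,
                 recomb_rate = recomb_rate, mut_rate = mut_rate,
                 sample_times = as.numeric(sample_times),
                 haploids_per_time = as.integer(haploids_per_time),
                 self_pair_most_recent = isTRUE(self_pair_most_recent),
                 seed = as.integer(seed)),
            class = "simulation_design")
}

# locate the python interpreter carrying msprime
find_python <- function() {
  py <- getOption("paleoclock.python", Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found; set options(paleoclock.python=)")
  py
}

# derive k sub-seeds (< 2^31) from a master seed
split_seed <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}

#' Simulate serially sampled haploid genomes
#'
#' Runs the bundled msprime backend: haploid lineages are sampled at
#' each design time point, chromosomes are simulated independently
#' under the scenario's demography with recombination and binary
#' (infinite-sites-like) mutation, and the genealogical truth (the
#' tree-span-weighted mean path length from the root to each sampled
#' lineage) is recorded. All simulated variants are treated as
#' transversions and are polarized to the simulator's true ancestral
#' allele.
#'
#' @param design A [simulation_design()].
#' @param scenario A [demography_scenario()].
#' @return A list with `calls` (haploids x sites 0/1 matrix), `sites`,
#'   `haploids` (data.frame: haploid, time), `path` (haploids x
#'   chromosomes matrix of mean root-to-sample path lengths in
#'   generations) and `chrom_lengths`.
#' @export
simulate_haploids <- function(design, scenario) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(scenario, "demography_scenario"))
  root_age <- max(design$sample_times)
  if (max(scenario$epochs$start_time) > 0 &&
      root_age < max(scenario$epochs$start_time)) {
    # allowed: epochs deeper than sampling are simply ancient history
  }
  py <- find_python()
  helper <- system.file("python", "serial_coalsim.py",
                        package = "paleoclock", mustWork = TRUE)
  out_dir <- tempfile("simdata")
  dir.create(out_dir)
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  seeds <- split_seed(design$seed, design$n_chromosomes)
  job <- list(
    out_dir = out_dir,
    chrom_lengths = rep(design$chrom_length, design$n_chromosomes),
    recomb_rate = design$recomb_rate,
    mut_rate = design$mut_rate,
    sample_times = design$sample_times,
    haploids_per_time = design$haploids_per_time,
    epochs = lapply(seq_len(nrow(scenario$epochs)), function(i) {
      list(start_time = scenario$epochs$start_time[i],
           ne = scenario$epochs$ne[i])
    }),
    seeds = seeds
  )
  job_file <- file.path(out_dir, "job.json")
  jsonlite::write_json(job, job_file, auto_unbox = TRUE, digits = NA)
  res <- suppressWarnings(
    system2(py, c(helper, job_file), stdout = TRUE, stderr = TRUE)
  )
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("coalescent backend failed:\n", paste(res, collapse = "\n"))
  }
  sites <- as.data.frame(data.table::fread(file.path(out_dir, "sites.tsv")))
  calls <- t(as.matrix(data.table::fread(file.path(out_dir, "calls.tsv"))))
  storage.mode(calls) <- "integer"
  haploids <- as.data.frame(
    data.table::fread(file.path(out_dir, "haploids.tsv")))
  rownames(calls) <- haploids$haploid
  truth <- as.data.frame(data.table::fread(file.path(out_dir, "truth.tsv")))
  chroms <- unique(sites$chrom)
  path <- matrix(NA_real_, nrow(haploids), length(chroms),
                 dimnames = list(haploids$haploid, chroms))
  path[cbind(match(truth$haploid, haploids$haploid),
             match(truth$chrom, chroms))] <- truth$mean_root_path
  chrom_lengths <- stats::setNames(
    truth$span_bp[match(chroms, truth$chrom)], chroms)
  list(calls = calls, sites = sites, haploids = haploids,
       path = path, chrom_lengths = chrom_lengths)
}

#' Pair haploid genomes into diploids
#'
#' Random pairing under random mating (each haploid used exactly once)
#' or self-pairing (each haploid duplicated into a fully homozygous
#' diploid, mimicking a completely inbred genome).
#'
#' @param haploid_ids Character vector of haploid ids to pair.
#' @param self_pair If `TRUE`, each haploid is paired with itself.
#' @param seed RNG seed for the random pairing.
#' @return data.frame with columns `hap_a`, `hap_b`.
#' @export
pair_haploids <- function(haploid_ids, self_pair = FALSE, seed = 1L) {
  n <- length(haploid_ids)
  if (self_pair) {
    return(data.frame(hap_a = haploid_ids, hap_b = haploid_ids))
  }
  if (n %% 2 != 0) stop("odd number of haploids with self_pair = FALSE")
  perm <- withr::with_seed(seed, sample(haploid_ids))
  data.frame(hap_a = perm[seq(1, n, 2)], hap_b = perm[seq(2, n, 2)])
}

#' Simulate a serially sampled diploid cohort with genealogical truth
#'
#' Runs [simulate_haploids()] and pairs the lineages of each time bin
#' into diploids: random pairing within every bin, except (by default)
#' the most recent bin, whose lineages are self-paired. The returned
#' truth table carries each diploid's sampling time and its mean
#' genealogical path length from the simulation root (averaged over
#' loci and over the two haploid genomes), the oracle against which
#' clock estimates are validated.
#'
#' @param design A [simulation_design()].
#' @param scenario A [demography_scenario()]; default constant size.
#' @return An object of class `diploid_cohort`: list with `hap1`,
#'   `hap2` (diploids x sites allele matrices), `sites`, `samples`
#'   (sample, time, hap_a, hap_b, self_paired), `path` (diploids x
#'   chromosomes truth matrix), `chrom_lengths`, `design`, `scenario`.
#' @export
simulate_cohort <- function(design,
                            scenario = scenario_library()[["constant"]]) {
  sim <- simulate_haploids(design, scenario)
  seeds <- split_seed(design$seed + 1L, length(design$sample_times))
  most_recent <- min(design$sample_times)
  pairs <- do.call(rbind, lapply(seq_along(design$sample_times), function(k) {
    tb <- design$sample_times[k]
    ids <- sim$haploids$haploid[sim$haploids$time == tb]
    self <- design$self_pair_most_recent && tb == most_recent
    p <- pair_haploids(ids, self_pair = self, seed = seeds[k])
    p$time <- tb
    p$self_paired <- self
    p
  }))
  pairs$sample <- sprintf("dip_t%d_%02d", pairs$time,
                          stats::ave(seq_len(nrow(pairs)), pairs$time,
                                     FUN = seq_along))
  ia <- match(pairs$hap_a, rownames(sim$calls))
  ib <- match(pairs$hap_b, rownames(sim$calls))
  hap1 <- sim$calls[ia, , drop = FALSE]
  hap2 <- sim$calls[ib, , drop = FALSE]
  rownames(hap1) <- rownames(hap2) <- pairs$sample
  path <- (sim$path[ia, , drop = FALSE] + sim$path[ib, , drop = FALSE]) / 2
  rownames(path) <- pairs$sample
  structure(list(hap1 = hap1, hap2 = hap2, sites = sim$sites,
                 samples = pairs[, c("sample", "time", "hap_a", "hap_b",
                                     "self_paired")],
                 path = path, chrom_lengths = sim$chrom_lengths,
                 design = design, scenario = scenario),
            class = "diploid_cohort")
}

#' @export
print.diploid_cohort <- function(x, ...) {
  cat("diploid_cohort:", nrow(x$hap1), "diploids x", ncol(x$hap1),
      "segregating sites,", length(x$chrom_lengths), "chromosome(s)\n")
  cat("  scenario:", x$scenario$id, "| sampling times:",
      paste(unique(x$samples$time), collapse = " "), "\n")
  invisible(x)
}

#' True mean genealogical path length for cohort samples
#'
#' The simulator's truth: the mean number of generations along the
#' genealogy from the root to the sampled genome, averaged over loci
#' (chromosomes weighted by length) and over the two haploid copies.
#' Its regression against sampling time has slope -1 by construction.
#'
#' @param cohort A `diploid_cohort` from [simulate_cohort()].
#' @param sample Sample id(s); default all.
#' @return Named numeric vector of path lengths in generations.
#' @export
true_path_generations <- function(cohort, sample = cohort$samples$sample) {
  stopifnot(inherits(cohort, "diploid_cohort"))
  unknown <- setdiff(sample, rownames(cohort$path))
  if (length(unknown)) stop("unknown sample id(s): ",
                            paste(unknown, collapse = ", "))
  w <- cohort$chrom_lengths / sum(cohort$chrom_lengths)
  drop(cohort$path[sample, , drop = FALSE] %*% w)
}

#' Pseudo-haploidize a diploid cohort into a site matrix
#'
#' One allele is drawn uniformly and independently at every site of
#' every diploid (the ancient-DNA single-read genotype proxy). The
#' resulting calls are already polarized, since the simulator's
#' ancestral allele is known exactly; callable length is the full
#' simulated genome, known per chromosome.
#'
#' @param cohort A `diploid_cohort`.
#' @param seed RNG seed for the allele draws (defaults to a seed
#'   derived from the design seed).
#' @return A [site_matrix()] with sample metadata columns `time` and
#'   `self_paired` and exact per-chromosome callable lengths.
#' @export
pseudo_haploidize_cohort <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "diploid_cohort"))
  if (is.null(seed)) seed <- split_seed(cohort$design$seed + 2L, 1)
  pick2 <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(length(cohort$hap1)) < 0.5, nrow = nrow(cohort$hap1))
  })
  calls <- cohort$hap1
  calls[pick2] <- cohort$hap2[pick2]
  chroms <- names(cohort$chrom_lengths)
  callable <- matrix(rep(cohort$chrom_lengths, each = nrow(calls)),
                     nrow = nrow(calls),
                     dimnames = list(rownames(calls), chroms))
  samples <- data.frame(sample = cohort$samples$sample,
                        group = cohort$scenario$id,
                        time = cohort$samples$time,
                        self_paired = cohort$samples$self_paired,
                        depth = 1)
  site_matrix(calls, cohort$sites, samples, callable)
}
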