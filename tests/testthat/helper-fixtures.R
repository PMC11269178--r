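# Shared fixtures. Simulated cohorts are cached per test run so
# several test files can reuse one coalescent simulation.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# desk-scale-but-small cohort: 2 chromosomes x 2 Mb, three time bins
tiny_design <- function(seed = 101, ...) {
  simulation_design(n_chromosomes = 2, chrom_length = 2e6,
                    sample_times = c(0, 300, 600),
                    haploids_per_time = 10, seed = seed, ...)
}

tiny_cohort <- function(seed = 101) {
  cached(paste0("tiny", seed), simulate_cohort(tiny_design(seed)))
}

# hand-built site matrix: explicit calls, uniform 1-based positions
toy_matrix <- function(calls, chrom = "chr1", pos = NULL,
                       ancestral = "A", derived = "T",
                       callable = 1e6) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 100L
  sites <- data.frame(chrom = chrom, pos = pos,
                      ancestral = ancestral, derived = derived)
  site_matrix(calls, sites, callable_length = callable)
}

# uniform 1 cM/Mb map over one 10-Mb chromosome
toy_map <- function(chroms = c(chr1 = 1e7)) {
  uniform_genetic_map(chroms, rate = 1e-8)
}

# brute-force pair-statistic oracle (double loop over pairs)
oracle_pair_counts <- function(calls, gpos_mM, edges) {
  nb <- length(edges) - 1
  np <- numeric(nb); nboth <- numeric(nb)
  n <- length(calls)
  for (i in seq_len(n - 1)) {
    if (is.na(calls[i])) next
    for (j in (i + 1):n) {
      if (is.na(calls[j])) next
      d <- abs(gpos_mM[j] - gpos_mM[i])
      if (d < edges[1] || d >= edges[nb + 1]) next
      b <- findInterval(d, edges)
      np[b] <- np[b] + 1
      if (calls[i] == 1 && calls[j] == 1) nboth[b] <- nboth[b] + 1
    }
  }
  cbind(pairs = np, both = nboth)
}

# synthetic trend data: generations-since-MRCA linear (or piecewise
# linear) in date, Gaussian noise at a stated jackknife SD
trend_data <- function(n = 200, gen_time = 8, sd = 20,
                       date_range = c(-15000, 0), t0 = 5000,
                       break_date = NULL, gen_time2 = NULL,
                       seed = 1) {
  withr::with_seed(seed, {
    date <- sort(stats::runif(n, date_range[1], date_range[2]))
    if (is.null(break_date)) {
      t_true <- t0 + (date - date_range[1]) / gen_time
    } else {
      t_true <- ifelse(
        date <= break_date,
        t0 + (date - date_range[1]) / gen_time,
        t0 + (break_date - date_range[1]) / gen_time +
          (date - break_date) / gen_time2)
    }
    data.frame(sample = sprintf("s%03d", seq_len(n)),
               t = t_true + stats::rnorm(n, 0, sd),
               date = date, weight = 1 / sd^2)
  })
}
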