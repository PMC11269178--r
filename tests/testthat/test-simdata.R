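test_that("scenario library and design validate their invariants", {
  lib <- scenario_library()
  expect_length(lib, 10)
  for (scn in lib) {
    expect_s3_class(scn, "demography_scenario")
    expect_equal(scn$epochs$start_time[1], 0)
    expect_true(all(diff(scn$epochs$start_time) > 0))
    expect_true(all(scn$epochs$ne > 0))
  }
  expect_error(demography_scenario("x", data.frame(start_time = 5, ne = 10)),
               "start at time 0")
  expect_error(demography_scenario("x", data.frame(start_time = c(0, 0),
                                                   ne = c(1, 1))),
               "strictly increasing")
  expect_error(simulation_design(haploids_per_time = 7), "even")
})

test_that("pairing conserves haploids; self-pairing duplicates them", {
  ids <- sprintf("h%02d", 1:20)
  p <- pair_haploids(ids, self_pair = FALSE, seed = 4)
  expect_equal(nrow(p), 10)
  expect_setequal(c(p$hap_a, p$hap_b), ids)
  expect_equal(anyDuplicated(c(p$hap_a, p$hap_b)), 0)
  ps <- pair_haploids(ids, self_pair = TRUE)
  expect_equal(nrow(ps), 20)
  expect_equal(ps$hap_a, ps$hap_b)
  expect_error(pair_haploids(ids[1:3], self_pair = FALSE), "odd")
  expect_identical(pair_haploids(ids, seed = 4), p)
})

test_that("cohort layout matches the serial design and is seed-stable", {
  coh <- tiny_cohort()
  # 3 time bins x 10 haploids: most recent self-paired -> 10 + 5 + 5
  expect_equal(nrow(coh$hap1), 20)
  expect_equal(as.integer(table(coh$samples$time)), c(10L, 5L, 5L))
  expect_true(all(coh$samples$self_paired[coh$samples$time == 0]))
  expect_false(any(coh$samples$self_paired[coh$samples$time > 0]))
  # self-paired diploids are fully homozygous
  sp <- coh$samples$sample[coh$samples$self_paired]
  expect_true(all(coh$hap1[sp, ] == coh$hap2[sp, ]))
  # determinism under the same seed
  coh2 <- simulate_cohort(tiny_design(101))
  expect_identical(coh$hap1, coh2$hap1)
  expect_identical(coh$sites, coh2$sites)
  expect_identical(coh$path, coh2$path)
  # different seed, different genealogy
  coh3 <- cached("tiny103", simulate_cohort(tiny_design(103)))
  expect_false(identical(dim(coh$hap1), dim(coh3$hap1)) &&
                 identical(coh$hap1, coh3$hap1))
})

test_that("truth paths are positive, ordered by age, offset by bin gap", {
  coh <- tiny_cohort()
  tp <- true_path_generations(coh)
  expect_true(all(tp > 0))
  by_bin <- tapply(tp, coh$samples$time, mean)
  # serial sampling: a lineage sampled s generations ago is s
  # generations closer to the root
  expect_equal(unname(by_bin["0"] - by_bin["600"]), 600, tolerance = 1e-6)
  expect_equal(unname(by_bin["0"] - by_bin["300"]), 300, tolerance = 1e-6)
  expect_error(true_path_generations(coh, "nope"), "unknown sample")
})

test_that("contemporaneous diversity matches the coalescent expectation", {
  # mean pairwise difference per bp among haploids ~ 4 Ne mu, averaged
  # over replicate seeds (analytic oracle for a constant-size
  # coalescent)
  mu <- 2.3e-8; ne <- 500
  des <- function(s) simulation_design(
    n_chromosomes = 1, chrom_length = 1e6, mut_rate = mu,
    sample_times = 0, haploids_per_time = 10,
    self_pair_most_recent = FALSE, seed = s)
  scn <- demography_scenario("ne500", data.frame(start_time = 0, ne = ne))
  pis <- vapply(1:20, function(s) {
    sim <- cached(paste0("pi", s), simulate_haploids(des(s), scn))
    g <- sim$calls
    n <- nrow(g)
    freq <- colMeans(g)
    # mean pairwise difference per bp (unbiased estimator)
    sum(2 * freq * (1 - freq) * n / (n - 1)) / 1e6
  }, numeric(1))
  expected <- 4 * ne * mu
  # Monte-Carlo tolerance: coalescent variance across single
  # chromosomes is large, hence 20 replicates and a generous band
  expect_equal(mean(pis), expected, tolerance = 0.25)
})

test_that("pseudo-haploidization is unbiased, seeded, and polarized", {
  coh <- tiny_cohort()
  sm <- pseudo_haploidize_cohort(coh, seed = 77)
  expect_s3_class(sm, "site_matrix")
  expect_identical(dim(sm$calls), dim(coh$hap1))
  # homozygous sites keep their allele with probability 1
  hom <- coh$hap1 == coh$hap2
  expect_true(all(sm$calls[hom] == coh$hap1[hom]))
  # heterozygous sites: derived fraction ~ 1/2 (binomial check over
  # all het sites in the cohort)
  het <- which(coh$hap1 != coh$hap2)
  if (length(het) > 1000) {
    frac <- mean(sm$calls[het] == 1)
    expect_true(abs(frac - 0.5) < 4 * sqrt(0.25 / length(het)))
  }
  # seeded reproducibility
  expect_identical(pseudo_haploidize_cohort(coh, seed = 77)$calls,
                   sm$calls)
  # callable length is the full simulated genome, per chromosome
  expect_equal(unname(sm$callable_length[1]),
               sum(coh$chrom_lengths))
  # mutation-clock oracle: pi / mu approximates the true path length
  cfg <- clock_config(mu = coh$design$mut_rate)
  g <- derived_fraction(sm) / cfg$mu
  tp <- true_path_generations(coh)
  expect_equal(unname(g), unname(tp[names(g)]), tolerance = 0.15)
})
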