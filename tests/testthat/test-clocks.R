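test_that("mutation clock is exact arithmetic in pi and mu", {
  cfg <- clock_config(mu = 2.3e-8)
  m0 <- toy_matrix(matrix(0L, 1, 5), callable = 1e7)
  expect_equal(mutation_clock(m0, cfg)$G_mut, 0)
  # 230 derived over 1e7 bp at mu = 2.3e-8 -> 1000 generations
  m1 <- toy_matrix(matrix(1L, 1, 230), pos = seq_len(230) * 10L,
                   callable = 1e7)
  expect_equal(mutation_clock(m1, cfg)$G_mut, 1000)
  # doubling mu halves G
  cfg2 <- clock_config(mu = 4.6e-8)
  expect_equal(mutation_clock(m1, cfg2)$G_mut, 500)
})

test_that("mutation-clock jackknife is zero for duplicated chromosomes", {
  calls <- cbind(matrix(c(1L, 0L, 1L), 3, 4), matrix(c(1L, 0L, 1L), 3, 4))
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), each = 4),
                      pos = rep(1:4 * 100L, 2),
                      ancestral = "A", derived = "T")
  cc <- matrix(5e5, 3, 2, dimnames = list(NULL, c("chr1", "chr2")))
  m <- site_matrix(calls, sites, callable_length = cc)
  mc <- mutation_clock(m, clock_config(mu = 1e-8))
  expect_equal(mc$var_jk, rep(0, 3), tolerance = 1e-18)
  expect_true(all(mutation_clock(m, clock_config(mu = 1e-8))$var_jk >= 0))
})

test_that("pair statistic equals the brute-force oracle exactly", {
  withr::with_seed(21, {
    n <- 400
    pos <- sort(sample.int(9e6, n))
    calls <- matrix(sample(c(0L, 1L, NA), n, TRUE, c(.5, .4, .1)), 1)
    rownames(calls) <- "s1"
    m <- toy_matrix(calls, pos = pos, callable = 1e7)
    map <- toy_map()
    cfg <- clock_config(mu = 1e-8, max_pairs_per_bin = Inf)
    cv <- pair_statistic(m, "s1", map, cfg)
    gpos <- interpolate_cM(map, "chr1", pos) * 10
    orc <- oracle_pair_counts(calls[1, ], gpos, cfg$bin_edges_mM)
    expect_equal(unname(cv$by_chrom[, "pairs", "chr1"]),
                 unname(orc[, "pairs"]))
    expect_equal(unname(cv$by_chrom[, "both", "chr1"]),
                 unname(orc[, "both"]))
    # normalized statistic definition
    pi_p <- sum(calls == 1L, na.rm = TRUE) / sum(!is.na(calls))
    expect_equal(cv$pi_panel, pi_p)
    ok <- cv$bins$n_pairs > 0
    expect_equal(cv$bins$N[ok],
                 (cv$bins$n_both[ok] / cv$bins$n_pairs[ok]) / pi_p)
  })
})

test_that("all-derived genome gives N = 1/pi in every occupied bin", {
  m <- toy_matrix(matrix(1L, 1, 50), pos = seq_len(50) * 1e5, callable = 1e7)
  map <- toy_map()
  cv <- pair_statistic(m, rownames(m$calls), map, clock_config(mu = 1e-8))
  ok <- cv$bins$n_pairs > 0
  expect_true(any(ok))
  expect_equal(cv$bins$N[ok], rep(1 / cv$pi_panel, sum(ok)))
})

test_that("masking and degenerate curves are handled", {
  calls <- rbind(s1 = rep(c(0L, 1L), 10))
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
                      pos = rep(1:10 * 1e5, 2),
                      ancestral = "A", derived = "T")
  m <- site_matrix(calls, sites, callable_length = 1e7)
  map <- toy_map(c(chr1 = 1e7, chr2 = 1e7))
  cfg <- clock_config(mu = 1e-8, masked_chromosomes = "chr2")
  cv <- pair_statistic(m, "s1", map, cfg)
  expect_equal(dimnames(cv$by_chrom)[[3]], "chr1")
  expect_error(pair_statistic(m, "s1", map,
                              clock_config(mu = 1e-8,
                                           masked_chromosomes = c("chr1", "chr2"))),
               "masked")
  z <- site_matrix(rbind(s1 = rep(0L, 20)), sites, callable_length = 1e7)
  expect_warning(pair_statistic(z, "s1", map, clock_config(mu = 1e-8)),
                 "no derived")
})

# build synthetic decay curves straight from the fitted model
model_curve <- function(sample, t, a, pi_panel, edges, n_pairs = 5e4,
                        chroms = c("chr1", "chr2")) {
  nb <- length(edges) - 1
  mids <- sqrt(edges[-1] * edges[-nb - 1])
  dM <- mids / 1000
  by_chrom <- array(0, dim = c(nb, 2, length(chroms)),
                    dimnames = list(NULL, c("pairs", "both"), chroms))
  for (ch in chroms) {
    p_both <- pi_panel * (pi_panel + a * exp(-dM * t))
    by_chrom[, "pairs", ch] <- n_pairs
    by_chrom[, "both", ch] <- n_pairs * p_both
  }
  tot <- apply(by_chrom, c(1, 2), sum)
  structure(list(sample = sample, pi_panel = pi_panel,
                 bins = data.frame(mid_mM = mids, n_pairs = tot[, 1],
                                   n_both = tot[, 2],
                                   N = (tot[, 2] / tot[, 1]) / pi_panel),
                 by_chrom = by_chrom),
            class = "pair_decay_curve")
}

test_that("noiseless model curves are recovered to optimizer tolerance", {
  cfg <- clock_config(mu = 2.3e-8)
  t_true <- c(s1 = 2000, s2 = 3500, s3 = 5000)
  curves <- lapply(names(t_true), function(s)
    model_curve(s, t_true[[s]], a = 0.04, pi_panel = 0.1,
                edges = cfg$bin_edges_mM))
  names(curves) <- names(t_true)
  fit <- fit_recombination_clock(curves, cfg)
  expect_true(fit$converged)
  expect_equal(setNames(fit$estimates$t_i, fit$estimates$sample),
               t_true, tolerance = 0.02)
  # T solves the ridge condition pulling the p_i towards 1:
  # sum r (r T - 1) = 0 for r = a_i / t_i
  r <- fit$estimates$p_i / fit$T
  expect_equal(fit$T, sum(r) / sum(r^2), tolerance = 1e-6)
  expect_true(all(fit$estimates$p_i > 0) && fit$T > 0)
})

test_that("a coarse grid oracle agrees with the 1-sample fit", {
  cfg <- clock_config(mu = 2.3e-8)
  cv <- model_curve("s1", 3000, a = 0.05, pi_panel = 0.12,
                    edges = cfg$bin_edges_mM)
  fit <- fit_recombination_clock(list(s1 = cv), cfg)
  # independent grid search over t with amplitude/intercept profiled
  # the same way a least-squares oracle would
  yw <- paleoclock:::curve_yw(cv)
  dM <- cv$bins$mid_mM / 1000
  grid <- exp(seq(log(500), log(2e4), length.out = 400))
  rss <- vapply(grid, function(t) {
    e <- exp(-dM * t)
    co <- stats::lm.wfit(cbind(1, e), yw[, "y"], yw[, "w"])$coefficients
    sum(yw[, "w"] * (yw[, "y"] - co[1] - co[2] * e)^2)
  }, numeric(1))
  t_oracle <- grid[which.min(rss)]
  expect_equal(fit$estimates$t_i, t_oracle, tolerance = 0.05)
  expect_equal(fit$estimates$t_i, 3000, tolerance = 0.05)
})

test_that("jackknife variance is ~0 for identical chromosomes, >= 0", {
  cfg <- clock_config(mu = 2.3e-8)
  curves <- list(s1 = model_curve("s1", 2500, 0.04, 0.1,
                                  cfg$bin_edges_mM),
                 s2 = model_curve("s2", 4000, 0.04, 0.1,
                                  cfg$bin_edges_mM))
  fit <- fit_recombination_clock(curves, cfg)
  jk <- jackknife_recclock(curves, fit)
  expect_true(all(jk$var_jk >= 0))
  # chromosomes carry identical information by construction
  expect_true(all(jk$var_jk < 1e-4 * jk$t_i^2))
  expect_error(jackknife_recclock(
    list(s1 = model_curve("s1", 2500, 0.04, 0.1, cfg$bin_edges_mM,
                          chroms = "chr1")),
    fit_recombination_clock(
      list(s1 = model_curve("s1", 2500, 0.04, 0.1, cfg$bin_edges_mM,
                            chroms = "chr1")), cfg)),
    "at least 2")
})

test_that("normalization keeps N stable under call downsampling", {
  # the pi division makes the pair curve invariant (in expectation) to
  # random call thinning of a genome
  coh <- tiny_cohort()
  sm <- pseudo_haploidize_cohort(coh)
  map <- uniform_genetic_map(coh$chrom_lengths, coh$design$recomb_rate)
  cfg <- clock_config(mu = coh$design$mut_rate)
  s <- coh$samples$sample[1]
  cv1 <- pair_statistic(sm, s, map, cfg)
  cv2 <- pair_statistic(downsample_calls(sm, 0.5, seed = 8), s, map, cfg)
  ok <- cv1$bins$n_pairs > 200 & cv2$bins$n_pairs > 200
  # short-range bins where the statistic is well estimated agree
  expect_true(any(ok))
  expect_equal(mean(cv2$bins$N[ok] - cv1$bins$N[ok]), 0, tolerance = 0.05)
})

test_that("run_clocks assembles both clocks on a simulated cohort", {
  coh <- tiny_cohort()
  sm <- pseudo_haploidize_cohort(coh)
  map <- uniform_genetic_map(coh$chrom_lengths, coh$design$recomb_rate)
  cfg <- clock_config(mu = coh$design$mut_rate)
  res <- run_clocks(sm, map, cfg, jackknife = TRUE)
  expect_true(all(c("G_mut", "t_i", "p_i", "var_jk_mut", "var_jk_rec")
                  %in% names(res$table)))
  expect_equal(nrow(res$table), nrow(sm$calls))
  expect_true(all(res$table$t_i > 0))
  expect_true(all(res$table$var_jk_rec >= 0, na.rm = TRUE))
  # the mutation clock tracks the genealogical truth on this cohort
  tp <- true_path_generations(coh)
  expect_true(cor(res$table$G_mut, tp[res$table$sample]) > 0.8)
})
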