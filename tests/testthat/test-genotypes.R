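test_that("site_matrix validates and derived_fraction computes", {
  m <- toy_matrix(rbind(a = c(0, 1, NA), b = c(1, 1, 0)),
                  callable = 1e7)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(derived_fraction(m)), c(1, 2) / 1e7)
  # forced arithmetic: 230 derived over 1e7 callable
  m2 <- toy_matrix(matrix(rep(1, 230), 1), pos = seq_len(230) * 10,
                   callable = 1e7)
  expect_equal(unname(derived_fraction(m2)), 2.3e-5)
  expect_error(toy_matrix(rbind(c(0, 2))), "0, 1 or NA")
  expect_error(derived_fraction(toy_matrix(rbind(c(0, 1)),
                                           callable = NULL)),
               "callable_length")
})

test_that("transversion filter keeps exactly the four transversion pairs", {
  calls <- matrix(0L, 2, 6)
  sites <- data.frame(chrom = "chr1", pos = 1:6 * 10,
                      ancestral = c("C", "A", "G", "G", "A", "T"),
                      derived   = c("T", "T", "C", "A", "C", "C"))
  m <- site_matrix(calls, sites)
  f <- filter_transversions(m)
  # C/T and G/A are transitions; T/C transition; A/T, G/C, A/C kept
  expect_equal(f$sites$ancestral, c("A", "G", "A"))
  expect_equal(ncol(f$calls), 3)
  # idempotent
  expect_identical(filter_transversions(f)$sites, f$sites)
})

test_that("missingness filter drops at 30% or more", {
  calls <- rbind(matrix(0L, 7, 3),
                 matrix(NA_integer_, 3, 3))  # 10 samples
  calls[8:10, 2] <- 0L   # site 2: 0/10 missing... adjust below
  calls[, 2] <- 0L
  calls[1:2, 3] <- NA_integer_
  # site 1: 3/10 missing (dropped at 0.30); site 2: 0 missing;
  # site 3: 5/10 missing (dropped)
  calls[1:7, 1] <- 0L; calls[8:10, 1] <- NA_integer_
  calls[3:7, 3] <- 0L; calls[8:10, 3] <- NA_integer_
  m <- toy_matrix(calls)
  f <- filter_missingness(m, 0.30)
  expect_equal(f$sites$pos, 200L)
  # 2/10 missing survives
  calls2 <- matrix(0L, 10, 1); calls2[1:2] <- NA_integer_
  expect_equal(ncol(filter_missingness(toy_matrix(calls2), 0.30)$calls), 1)
  # boundary: max_missing = 1 keeps sites with any called sample
  expect_equal(ncol(filter_missingness(toy_matrix(calls2), 1)$calls), 1)
  # idempotent
  expect_identical(filter_missingness(f, 0.3)$sites, f$sites)
})

test_that("adjacent-site thinning keeps one site per adjacency run", {
  m <- toy_matrix(matrix(0L, 1, 3), pos = c(100L, 101L, 150L))
  t1 <- thin_adjacent(m, seed = 1)
  expect_equal(ncol(t1$calls), 2)
  expect_true(150 %in% t1$sites$pos)
  expect_true(any(c(100, 101) %in% t1$sites$pos))
  # run of three adjacent -> exactly one kept
  m2 <- toy_matrix(matrix(0L, 1, 3), pos = c(7L, 8L, 9L))
  expect_equal(ncol(thin_adjacent(m2, 1)$calls), 1)
  # property: output count equals number of adjacency runs; no two
  # retained sites adjacent
  withr::with_seed(3, {
    for (rep in 1:20) {
      pos <- sort(sample.int(60, 25))
      mm <- toy_matrix(matrix(0L, 1, 25), pos = pos)
      runs <- sum(diff(pos) > 1) + 1
      th <- thin_adjacent(mm, seed = rep)
      expect_equal(ncol(th$calls), runs)
      expect_true(all(diff(th$sites$pos) > 1))
      # idempotence
      expect_identical(thin_adjacent(th, seed = rep)$sites, th$sites)
    }
  })
  # unchanged when nothing adjacent
  m3 <- toy_matrix(matrix(0L, 1, 4), pos = c(10L, 20L, 30L, 40L))
  expect_identical(thin_adjacent(m3, 1)$sites, m3$sites)
})

test_that("outgroup polarization orients, drops disagreement", {
  calls <- rbind(s1 = c(0L, 0L, 0L, 1L), s2 = c(1L, 1L, 1L, 0L))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                      ancestral = c("A", "A", "A", "G"),
                      derived = c("T", "T", "T", "T"))
  m <- site_matrix(calls, sites)
  og <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                   og1 = c("A", "A", "G", "T"),
                   og2 = c("A", "C", "G", "T"),
                   og3 = c("A", "A", "G", "T"))
  # site 10: outgroups agree on A (current ancestral) -> kept as is
  # site 20: outgroups disagree -> dropped
  # site 30: agree on G, not among alleles -> dropped
  # site 40: agree on T = current derived -> kept, flipped
  suppressMessages(p <- polarize(m, og))
  expect_equal(p$sites$pos, c(10L, 40L))
  expect_equal(p$sites$ancestral, c("A", "T"))
  expect_equal(p$sites$derived, c("T", "G"))
  expect_equal(unname(p$calls[, 2]), c(0L, 1L))  # flipped calls
  expect_equal(unname(p$calls[, 1]), c(0L, 1L))  # unchanged
  # missing outgroups: one informative outgroup suffices by default
  og2 <- data.frame(chrom = "chr1", pos = 10L, og1 = "A",
                    og2 = NA, og3 = ".")
  m1 <- m[, 1]
  expect_equal(ncol(polarize(m1, og2)$calls), 1)
  suppressMessages(
    expect_equal(ncol(polarize(m1, og2, require_all = TRUE)$calls), 0))
})

test_that("pseudo-haploid calls honour the two-read rule", {
  expect_true(is.na(pseudo_haploid_call(1, 0, seed = 1)))
  expect_true(is.na(pseudo_haploid_call(0, 1, seed = 1)))
  expect_equal(pseudo_haploid_call(0, 5, seed = 1), 1L)
  expect_equal(pseudo_haploid_call(4, 0, seed = 1), 0L)
  # balanced reads -> derived fraction near 1/2 (binomial check)
  calls <- pseudo_haploid_call(rep(3, 1e4), rep(3, 1e4), seed = 42)
  expect_true(abs(mean(calls) - 0.5) < 3 * sqrt(0.25 / 1e4))
  expect_identical(pseudo_haploid_call(rep(3, 50), rep(3, 50), seed = 9),
                   pseudo_haploid_call(rep(3, 50), rep(3, 50), seed = 9))
})

test_that("call downsampling is binomial, seeded and rescales metadata", {
  m <- toy_matrix(matrix(1L, 10, 1000), pos = seq_len(1000) * 10,
                  callable = 1e6)
  expect_identical(downsample_calls(m, 1)$calls, m$calls)
  d <- downsample_calls(m, 0.5, seed = 3)
  kept <- sum(!is.na(d$calls))
  expect_true(abs(kept - 5000) < 4 * sqrt(10000 * 0.25))
  expect_identical(downsample_calls(m, 0.5, seed = 3)$calls, d$calls)
  expect_equal(unname(d$callable_length[1]), 5e5)
})

test_that("canonical pipeline is monotone non-increasing in sites", {
  coh <- tiny_cohort()
  sm <- pseudo_haploidize_cohort(coh)
  f <- filter_pipeline(sm, max_missing = 0.3, seed = 2)
  rep <- attr(f, "filter_report")
  expect_true(all(diff(rep$n_sites) <= 0))
  expect_equal(rep$stage[1], "input")
})
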