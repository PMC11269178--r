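#' Two-allele draws per site (pseudo-heterozygosity substrate)
#'
#' The inbreeding proxy used for low-coverage genomes compares two
#' alleles sampled independently at each site: two sequencing reads in
#' real data, or two draws (with replacement) from the diploid genotype
#' in synthetic data, so a true heterozygous site yields mismatching
#' draws with probability 1/2. This function produces the synthetic
#' version from a diploid cohort.
#'
#' @param cohort A `diploid_cohort` from [simulate_cohort()].
#' @param seed RNG seed.
#' @return Integer matrix (samples x sites): 1 where the two draws
#'   mismatch, 0 where they agree.
#' @export
two_allele_draws <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "diploid_cohort"))
  withr::with_seed(as.integer(seed), {
    n <- length(cohort$hap1)
    d1 <- matrix(stats::runif(n) < 0.5, nrow = nrow(cohort$hap1))
    d2 <- matrix(stats::runif(n) < 0.5, nrow = nrow(cohort$hap1))
    a1 <- ifelse(d1, cohort$hap1, cohort$hap2)
    a2 <- ifelse(d2, cohort$hap1, cohort$hap2)
    out <- (a1 != a2) * 1L
    dimnames(out) <- dimnames(cohort$hap1)
    out
  })
}

#' Windowed pseudo-heterozygosity profile
#'
#' Bins per-site mismatch indicators (from two reads or two genotype
#' draws, see [two_allele_draws()]) into fixed genetic windows and
#' computes the pseudo-heterozygosity rate per window: mismatching
#' sites / informative sites. Windows with fewer than `min_sites`
#' informative sites are set to `NA` -- sparse windows cannot support a
#' homozygosity call and later break runs of homozygosity rather than
#' bridging them.
#'
#' @param mismatch Integer/logical matrix (samples x sites): 1 =
#'   mismatching draws, 0 = matching, NA = uninformative site.
#' @param sites data.frame with `chrom`, `pos` for the columns of
#'   `mismatch`.
#' @param map A [genetic_map()].
#' @param windows Output of [make_windows()]; defaults to 1-cM windows
#'   over `map`.
#' @param min_sites Minimum informative sites per window (default 20).
#' @return An object of class `het_profile`: list with `rates` and
#'   `n_sites` (samples x windows matrices) and `windows`.
#' @export
pseudo_het_profile <- function(mismatch, sites, map,
                               windows = make_windows(map),
                               min_sites = 20) {
  stopifnot(inherits(map, "genetic_map"),
            ncol(mismatch) == nrow(sites))
  widx <- window_of(map, windows, sites$chrom, sites$pos)
  nw <- nrow(windows)
  wf <- factor(widx, levels = seq_len(nw))
  inf <- !is.na(mismatch)
  n_sites <- t(apply(inf, 1, function(r) tapply(r, wf, sum, default = 0)))
  n_mis <- t(apply(mismatch, 1, function(r)
    tapply(r, wf, sum, na.rm = TRUE, default = 0)))
  n_sites[is.na(n_sites)] <- 0
  n_mis[is.na(n_mis)] <- 0
  rates <- ifelse(n_sites >= min_sites, n_mis / pmax(n_sites, 1), NA)
  rownames(rates) <- rownames(n_sites) <- rownames(mismatch)
  structure(list(rates = rates, n_sites = n_sites, windows = windows,
                 min_sites = min_sites),
            class = "het_profile")
}

#' @export
print.het_profile <- function(x, ...) {
  cat("het_profile:", nrow(x$rates), "samples x", ncol(x$rates),
      "windows;", sprintf("%.1f%%", 100 * mean(is.na(x$rates))),
      "windows below", x$min_sites, "informative sites\n")
  invisible(x)
}

#' Call runs of homozygosity from a pseudo-heterozygosity profile
#'
#' A window belongs to a run of homozygosity (ROH) when its
#' pseudo-heterozygosity rate is strictly below `threshold` (a window
#' at exactly the threshold is not a ROH). Maximal runs of contiguous
#' ROH windows on a chromosome are merged into segments; windows with
#' missing rates break runs. Segment bounds are window bounds (no
#' sub-window refinement).
#'
#' @param profile A [pseudo_het_profile()].
#' @param threshold ROH pseudo-heterozygosity threshold (default
#'   0.005).
#' @return data.frame of segments: `sample`, `chrom`, `start_cM`,
#'   `end_cM`, `start_bp`, `end_bp`, `length_cM`, `n_windows`.
#' @export
call_roh <- function(profile, threshold = 0.005) {
  stopifnot(inherits(profile, "het_profile"))
  w <- profile$windows
  out <- list()
  for (s in rownames(profile$rates)) {
    r <- profile$rates[s, ]
    is_roh <- !is.na(r) & r < threshold
    for (ch in unique(w$chrom)) {
      wi <- which(w$chrom == ch)
      rr <- rle(is_roh[wi])
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths + 1
      for (k in which(rr$values)) {
        i0 <- wi[starts[k]]; i1 <- wi[ends[k]]
        out[[length(out) + 1]] <- data.frame(
          sample = s, chrom = ch,
          start_cM = w$start_cM[i0], end_cM = w$end_cM[i1],
          start_bp = w$start_bp[i0], end_bp = w$end_bp[i1],
          length_cM = w$end_cM[i1] - w$start_cM[i0],
          n_windows = ends[k] - starts[k] + 1L)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      start_bp = numeric(), end_bp = numeric(),
                      length_cM = numeric(), n_windows = integer()))
  }
  do.call(rbind, out)
}

#' Genome fractions in ROH size classes and the close-kin flag
#'
#' Bins each sample's ROH segments into genetic-length classes
#' (default `[1,2)`, `[2,4)`, `[4,8)`, `[8,15)`, `[15,Inf)` cM) and
#' reports the fraction of the mapped genome they span. Long ROHs (at
#' least 15 cM by default) arise when the two parental genomes share a
#' very recent ancestor, so any genome span in the top class raises the
#' close-kin mating flag.
#'
#' @param segments Segment table from [call_roh()].
#' @param genome_span_cM Total mapped genome length in cM (e.g.
#'   `sum(windows$end_cM - windows$start_cM)`).
#' @param breaks Lower class bounds plus `Inf` (default
#'   `c(1, 2, 4, 8, 15, Inf)`); segments shorter than the first bound
#'   are ignored.
#' @param samples Optional sample ids to report (so samples without
#'   segments still appear).
#' @return data.frame with one row per sample: fraction per class,
#'   `total_roh_cM`, `froh` (total fraction in counted classes) and
#'   `close_kin` (`TRUE` iff the top class is non-empty).
#' @export
summarize_roh <- function(segments, genome_span_cM,
                          breaks = c(1, 2, 4, 8, 15, Inf),
                          samples = NULL) {
  stopifnot(genome_span_cM > 0, length(breaks) >= 2,
            all(diff(breaks) > 0))
  if (is.null(samples)) samples <- unique(segments$sample)
  labs <- paste0("[", breaks[-length(breaks)], ",",
                 ifelse(is.finite(breaks[-1]), breaks[-1], "Inf"), ")")
  out <- lapply(samples, function(s) {
    len <- segments$length_cM[segments$sample == s]
    len <- len[len >= breaks[1]]
    cls <- cut(len, breaks, right = FALSE, labels = labs)
    by_class <- tapply(len, cls, sum, default = 0) / genome_span_cM
    by_class[is.na(by_class)] <- 0
    df <- as.data.frame(as.list(by_class), check.names = FALSE)
    df$sample <- s
    df$total_roh_cM <- sum(len)
    df$froh <- sum(by_class)
    df$close_kin <- unname(by_class[length(by_class)] > 0)
    df
  })
  out <- do.call(rbind, out)
  out[, c("sample", labs, "total_roh_cM", "froh", "close_kin")]
}

#' Windowed inbreeding pipeline for a simulated cohort
#'
#' Convenience wrapper for synthetic data: two-allele draws,
#' 1-cM-window pseudo-heterozygosity, ROH calling and size-class
#' summary.
#'
#' @param cohort A `diploid_cohort`.
#' @param map A [genetic_map()] (default: uniform map at the design's
#'   recombination rate).
#' @param threshold ROH threshold for [call_roh()].
#' @param min_sites Minimum informative sites per window.
#' @param seed Seed for the allele draws.
#' @return A list with `profile`, `segments`, `summary`,
#'   `genome_span_cM`.
#' @export
roh_pipeline <- function(cohort,
                         map = uniform_genetic_map(cohort$chrom_lengths,
                                                   cohort$design$recomb_rate),
                         threshold = 0.005, min_sites = 20, seed = 1L) {
  mm <- two_allele_draws(cohort, seed)
  windows <- make_windows(map)
  prof <- pseudo_het_profile(mm, cohort$sites, map, windows, min_sites)
  segs <- call_roh(prof, threshold)
  span <- sum(windows$end_cM - windows$start_cM)
  list(profile = prof, segments = segs,
       summary = summarize_roh(segs, span,
                               samples = rownames(cohort$hap1)),
       genome_span_cM = span)
}
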