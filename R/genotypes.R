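#' Read pseudo-haploid or diploid genotypes from a VCF file
#'
#' Builds a [site_matrix()] from the GT field of a VCF. Haploid calls
#' map directly to 0/1; diploid heterozygotes are resolved by a seeded
#' uniform draw of one allele (mirroring pseudo-haploidization) unless
#' `het_as_missing = TRUE`. Multi-allelic sites (more than one ALT
#' allele) are dropped with a message. At this stage alleles are
#' REF/ALT-coded (0 = REF, 1 = ALT); use [polarize()] to orient them as
#' ancestral/derived.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_subset Optional character vector of sample ids to
#'   keep.
#' @param het_as_missing Set diploid heterozygotes to `NA` instead of
#'   drawing one allele.
#' @param seed Seed for the heterozygote draw.
#' @param callable_length Optional callable length passed to
#'   [site_matrix()].
#' @return A [site_matrix()] whose `sites$ancestral`/`derived` hold the
#'   REF/ALT alleles.
#' @export
read_vcf <- function(path, sample_subset = NULL, het_as_missing = FALSE,
                     seed = 1L, callable_length = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1
  if (any(multi)) {
    message("dropping ", sum(multi), " multi-allelic site(s)")
  }
  keep <- !multi & n_alt == 1
  vcf <- vcf[keep, ]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, colnames(gt))
    if (length(missing_s)) stop("samples not in VCF: ",
                                paste(missing_s, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
  }
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ancestral = as.character(VariantAnnotation::ref(vcf)),
    derived = as.character(unlist(VariantAnnotation::alt(vcf)))
  )
  calls <- withr::with_seed(seed, {
    vapply(seq_len(ncol(gt)), function(j)
      decode_gt(gt[, j], het_as_missing), integer(nrow(gt)))
  })
  calls <- matrix(as.integer(calls), nrow = ncol(gt), byrow = TRUE,
                  dimnames = list(colnames(gt), NULL))  # samples x sites
  site_matrix(calls, sites,
              samples = data.frame(sample = rownames(calls)),
              callable_length = callable_length)
}

# GT strings -> 0/1/NA; het resolved by a uniform draw unless asked not to
decode_gt <- function(g, het_as_missing) {
  a <- strsplit(g, "[/|]")
  vapply(a, function(al) {
    al <- al[al != "."]
    if (length(al) == 0) return(NA_integer_)
    al <- as.integer(al)
    if (length(al) == 1) return(al)
    if (al[1] == al[2]) return(al[1])
    if (het_as_missing) return(NA_integer_)
    al[sample.int(2L, 1L)]
  }, integer(1))
}

#' Write a site matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with one pseudo-haploid GT column per sample
#' (`0`, `1` or `.`); REF holds the ancestral allele and ALT the
#' derived allele, so a round trip through [read_vcf()] plus
#' [polarize()] is the identity.
#'
#' @param x A [site_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "site_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=paleoclock",
               paste0("##contig=<ID=", unique(x$sites$chrom), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(x$calls)),
                     collapse = "\t")), con)
  gt <- t(x$calls)  # sites x samples
  gt_chr <- matrix(as.character(gt), nrow = nrow(gt))
  gt_chr[is.na(gt)] <- "."
  body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ancestral,
                x$sites$derived, ".", ".", ".", "GT",
                apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Polarize alleles using an outgroup panel
#'
#' Orients each site's alleles as ancestral/derived using the allele
#' shared by the outgroup lineages: a site is kept when all non-missing
#' outgroups carry the same allele and that allele is one of the site's
#' two alleles; any outgroup disagreement, or an outgroup allele not
#' segregating at the site, drops the site. Calls at sites whose
#' current 0-allele is not the outgroup allele are flipped. With
#' `require_all = TRUE`, sites missing any outgroup are dropped too.
#'
#' @param x A [site_matrix()] (0 = `sites$ancestral` allele as read,
#'   e.g. REF).
#' @param outgroups data.frame with columns `chrom`, `pos` and one
#'   column per outgroup lineage holding single-base alleles (`NA` or
#'   `"."` for missing).
#' @param require_all Require every outgroup column to be non-missing.
#' @return A polarized [site_matrix()]; dropped-site counts are
#'   reported with `message()`.
#' @export
polarize <- function(x, outgroups, require_all = FALSE) {
  stopifnot(inherits(x, "site_matrix"),
            all(c("chrom", "pos") %in% names(outgroups)))
  og_cols <- setdiff(names(outgroups), c("chrom", "pos"))
  if (length(og_cols) == 0) stop("outgroup panel has no allele columns")
  key_x <- paste(x$sites$chrom, x$sites$pos)
  key_o <- paste(as.character(outgroups$chrom), outgroups$pos)
  idx <- match(key_x, key_o)
  og <- as.matrix(outgroups[idx, og_cols, drop = FALSE])
  og[og == "."] <- NA
  n_miss <- rowSums(is.na(og))
  anc <- apply(og, 1, function(a) {
    a <- a[!is.na(a)]
    if (length(a) == 0) return(NA_character_)
    u <- unique(a)
    if (length(u) == 1) u else NA_character_  # disagreement
  })
  ok <- !is.na(anc) & (anc == x$sites$ancestral | anc == x$sites$derived)
  if (require_all) ok <- ok & n_miss == 0
  ok[is.na(idx)] <- FALSE
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    message("polarize: dropping ", n_drop,
            " site(s) without a consistent outgroup allele")
  }
  flip <- ok & anc == x$sites$derived
  calls <- x$calls
  calls[, which(flip)] <- 1L - calls[, which(flip), drop = FALSE]
  sites <- x$sites
  der <- ifelse(flip, sites$ancestral, sites$derived)
  sites$ancestral[flip] <- sites$derived[flip]
  sites$derived <- der
  out <- x
  out$calls <- calls[, ok, drop = FALSE]
  out$sites <- sites[ok, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

#' Keep transversion sites only
#'
#' Transversions (purine/pyrimidine changes: A/C, A/T, G/C, G/T) are
#' immune to post-mortem cytosine deamination and are the standard
#' ancient-DNA site set; transitions are removed.
#'
#' @param x A [site_matrix()].
#' @return A [site_matrix()] restricted to transversion sites.
#' @export
filter_transversions <- function(x) {
  stopifnot(inherits(x, "site_matrix"))
  pur <- c("A", "G")
  a <- toupper(x$sites$ancestral)
  d <- toupper(x$sites$derived)
  keep <- (a %in% pur) != (d %in% pur)
  x[, keep]
}

#' Drop sites with excessive missingness
#'
#' A site is removed when the fraction of samples with a missing call
#' is greater than or equal to `max_missing` (so the default drops
#' sites uncovered in 30% or more of the samples; a site with 3 of 10
#' samples missing is dropped).
#'
#' @param x A [site_matrix()].
#' @param max_missing Missingness threshold in (0, 1].
#' @return A filtered [site_matrix()].
#' @export
filter_missingness <- function(x, max_missing = 0.30) {
  stopifnot(inherits(x, "site_matrix"),
            max_missing > 0, max_missing <= 1)
  frac <- colMeans(is.na(x$calls))
  x[, frac < max_missing]
}

#' Thin runs of adjacent sites to one site each
#'
#' Where two or more retained sites occupy consecutive bp positions
#' (likely artefacts of a single mutational or alignment event),
#' exactly one site per maximal run of adjacent positions is kept,
#' chosen uniformly with a seeded RNG.
#'
#' @param x A [site_matrix()].
#' @param seed RNG seed for the within-run choice.
#' @return A thinned [site_matrix()]; no two retained sites on a
#'   chromosome are at consecutive positions.
#' @export
thin_adjacent <- function(x, seed = 1L) {
  stopifnot(inherits(x, "site_matrix"))
  run <- cumsum(c(TRUE, !(diff(x$sites$pos) == 1 &
                            x$sites$chrom[-1] ==
                              x$sites$chrom[-nrow(x$sites)])))
  keep <- withr::with_seed(seed, {
    vapply(split(seq_along(run), run), function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
  })
  x[, sort(unname(keep))]
}

#' Pseudo-haploid call from per-allele read counts
#'
#' The standard low-coverage ancient-DNA genotype proxy: one sequencing
#' read is drawn uniformly among the reads covering a site and its
#' allele is reported, provided the site carries at least `min_reads`
#' reads (base-quality filtering is assumed upstream).
#'
#' @param n_ancestral,n_derived Read counts supporting each allele
#'   (vectors recycle).
#' @param min_reads Minimum total reads for a call (default 2).
#' @param seed RNG seed.
#' @return Integer vector of calls in `{0, 1, NA}`.
#' @export
pseudo_haploid_call <- function(n_ancestral, n_derived, min_reads = 2,
                                seed = 1L) {
  stopifnot(all(n_ancestral >= 0), all(n_derived >= 0))
  n <- max(length(n_ancestral), length(n_derived))
  n_ancestral <- rep_len(n_ancestral, n)
  n_derived <- rep_len(n_derived, n)
  tot <- n_ancestral + n_derived
  withr::with_seed(seed, {
    out <- ifelse(tot < min_reads, NA_integer_,
                  as.integer(stats::runif(n) < n_derived / tot))
    out
  })
}

#' Randomly set calls to missing (depth downsampling emulation)
#'
#' Emulates, at the call level, downsampling of all samples to a common
#' depth of coverage: every call is independently retained with
#' probability `keep_prob`, and each sample's callable length and depth
#' proxy are rescaled by the same factor.
#'
#' @param x A [site_matrix()].
#' @param keep_prob Retention probability in (0, 1].
#' @param seed RNG seed.
#' @return A [site_matrix()] with additional missingness.
#' @export
downsample_calls <- function(x, keep_prob, seed = 1L) {
  stopifnot(inherits(x, "site_matrix"), keep_prob > 0, keep_prob <= 1)
  if (keep_prob == 1) return(x)
  out <- x
  mask <- withr::with_seed(seed, {
    matrix(stats::runif(length(x$calls)) >= keep_prob, nrow = nrow(x$calls))
  })
  out$calls[mask] <- NA_integer_
  if (!is.null(out$callable_length)) {
    out$callable_length <- out$callable_length * keep_prob
  }
  if (!is.null(out$chrom_callable)) {
    out$chrom_callable <- out$chrom_callable * keep_prob
  }
  if (!is.null(out$samples$depth)) {
    out$samples$depth <- out$samples$depth * keep_prob
  }
  out
}

#' Canonical site-filter pipeline
#'
#' Applies the standard filters in their canonical order --
#' transversions, outgroup polarization, missingness, adjacent-site
#' thinning -- and reports per-stage site counts.
#'
#' @param x A [site_matrix()].
#' @param outgroups Optional outgroup panel for [polarize()]; skipped
#'   when `NULL` (synthetic data is already polarized).
#' @param max_missing Threshold for [filter_missingness()].
#' @param seed Seed for [thin_adjacent()].
#' @return The filtered [site_matrix()], with a `filter_report`
#'   attribute (data.frame of stage and sites remaining).
#' @export
filter_pipeline <- function(x, outgroups = NULL, max_missing = 0.30,
                            seed = 1L) {
  report <- data.frame(stage = "input", n_sites = ncol(x$calls))
  x <- filter_transversions(x)
  report <- rbind(report, data.frame(stage = "transversions",
                                     n_sites = ncol(x$calls)))
  if (!is.null(outgroups)) {
    x <- polarize(x, outgroups)
    report <- rbind(report, data.frame(stage = "polarize",
                                       n_sites = ncol(x$calls)))
  }
  x <- filter_missingness(x, max_missing)
  report <- rbind(report, data.frame(stage = "missingness",
                                     n_sites = ncol(x$calls)))
  x <- thin_adjacent(x, seed)
  report <- rbind(report, data.frame(stage = "thin_adjacent",
                                     n_sites = ncol(x$calls)))
  attr(x, "filter_report") <- report
  x
}
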