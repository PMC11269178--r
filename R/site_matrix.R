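#' Pseudo-haploid site matrix
#'
#' The central container of the package: per-sample, per-site
#' pseudo-haploid calls polarized against an ancestral sequence. Calls
#' are coded `0` (ancestral allele), `1` (derived allele) or `NA`
#' (missing). Sites carry 1-based physical coordinates and their
#' ancestral/derived alleles; samples carry metadata (group label,
#' calendar date, depth-of-coverage proxy) and a callable genome length
#' used as the denominator of the per-genome derived-mutation density
#' (the mutation-clock input), which must count every assayed base,
#' monomorphic positions included -- restricting it to the variant
#' panel would make the clock ascertainment-dependent.
#'
#' @param calls Integer matrix, samples in rows, sites in columns,
#'   entries in `{0, 1, NA}`. Row names are sample ids.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ancestral`, `derived` (single bases), one row per column of
#'   `calls`, ordered by chromosome then position (strictly increasing
#'   within chromosome).
#' @param samples Optional data.frame of sample metadata with at least
#'   a `sample` column matching `rownames(calls)`; columns `group`,
#'   `date`, `depth` are used downstream when present.
#' @param callable_length Numeric vector (one per sample, recycled if
#'   length 1): callable genome length in bp. May instead be a matrix
#'   samples x chromosomes to make leave-one-chromosome-out estimates
#'   exact.
#' @return An object of class `site_matrix`.
#' @export
site_matrix <- function(calls, sites, samples = NULL,
                        callable_length = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos") %in% names(sites)),
            nrow(sites) == ncol(calls))
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  }
  if (!all(calls %in% c(0L, 1L, NA_integer_))) {
    stop("calls must be 0, 1 or NA")
  }
  sites$chrom <- as.character(sites$chrom)
  if (is.null(sites$ancestral)) sites$ancestral <- "A"
  if (is.null(sites$derived)) sites$derived <- "T"
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord, strictly = TRUE)) {
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("site positions not strictly increasing on ", ch)
    }
  }
  rownames(sites) <- NULL
  if (is.null(samples)) {
    samples <- data.frame(sample = rownames(calls))
  }
  stopifnot(all(rownames(calls) %in% samples$sample))
  samples <- samples[match(rownames(calls), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  chrom_callable <- NULL
  if (!is.null(callable_length)) {
    if (is.matrix(callable_length)) {
      stopifnot(nrow(callable_length) == nrow(calls))
      chrom_callable <- callable_length
      rownames(chrom_callable) <- rownames(calls)
      callable_length <- rowSums(chrom_callable)
    } else {
      callable_length <- rep_len(as.numeric(callable_length), nrow(calls))
    }
    names(callable_length) <- rownames(calls)
  }
  structure(list(calls = calls, sites = sites, samples = samples,
                 callable_length = callable_length,
                 chrom_callable = chrom_callable),
            class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat("site_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "sites on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness %.1f%%; callable length %s\n", 100 * miss,
              if (is.null(x$callable_length)) "unset" else
                format(stats::median(x$callable_length), big.mark = ",")))
  invisible(x)
}

#' @export
dim.site_matrix <- function(x) dim(x$calls)

#' Subset a site matrix by samples and/or sites
#'
#' @param x A [site_matrix()].
#' @param i Sample selector (ids, indices or logical).
#' @param j Site selector (indices or logical).
#' @param ... Unused.
#' @return A [site_matrix()] restricted to the selection.
#' @export
`[.site_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, rownames(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  cl <- x$callable_length
  if (!is.null(cl)) cl <- cl[rownames(calls)]
  cc <- x$chrom_callable
  if (!is.null(cc)) cc <- cc[rownames(calls), , drop = FALSE]
  out <- site_matrix(calls, x$sites[j, , drop = FALSE],
                     x$samples[i, , drop = FALSE], cl)
  out$chrom_callable <- cc
  out
}

#' Keep only the listed chromosomes of a site matrix
#'
#' @param x A [site_matrix()].
#' @param chroms Chromosome ids to keep (or drop).
#' @param drop If `TRUE`, `chroms` lists chromosomes to remove instead.
#' @return A [site_matrix()].
#' @export
subset_chromosomes <- function(x, chroms, drop = FALSE) {
  keep <- if (drop) !(x$sites$chrom %in% chroms) else x$sites$chrom %in% chroms
  out <- x[, keep]
  cc <- out$chrom_callable
  if (!is.null(cc)) {
    kc <- if (drop) setdiff(colnames(cc), chroms) else
      intersect(colnames(cc), chroms)
    out$chrom_callable <- cc[, kc, drop = FALSE]
    out$callable_length <- rowSums(out$chrom_callable)
  }
  out
}

#' Per-genome derived-mutation density
#'
#' The proportion of a genome's callable length carrying the derived
#' allele: the per-sample count of derived calls divided by the
#' callable genome length (assayed bases, monomorphic included).
#' Missing calls do not contribute to the numerator; the denominator is
#' a property of the assay, not of the variant panel.
#'
#' @param x A [site_matrix()] with `callable_length` set.
#' @param sample Sample id(s); default all samples.
#' @return Named numeric vector of derived fractions (per bp).
#' @export
derived_fraction <- function(x, sample = rownames(x$calls)) {
  stopifnot(inherits(x, "site_matrix"))
  if (is.null(x$callable_length)) {
    stop("callable_length is required to compute a derived fraction")
  }
  if (any(x$callable_length[sample] <= 0)) {
    stop("callable_length must be positive")
  }
  d <- rowSums(x$calls[sample, , drop = FALSE] == 1L, na.rm = TRUE)
  d / x$callable_length[sample]
}
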