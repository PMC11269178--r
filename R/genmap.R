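#' Genetic map from physical/genetic anchor positions
#'
#' A genetic map stores, per chromosome, an ordered set of anchors
#' pairing a physical position (bp) with a cumulative genetic position
#' (cM). Genetic positions between anchors are obtained by linear
#' interpolation; positions outside the anchored span are clamped to
#' the terminal anchor's cM, so that unmapped chromosome ends fall into
#' the terminal windows rather than extrapolating recombination where
#' the map has no information.
#'
#' @param anchors A data.frame with columns `chrom`, `pos` (bp,
#'   1-based) and `cM` (cumulative genetic position). Within each
#'   chromosome, `pos` must be strictly increasing and `cM`
#'   non-decreasing, with at least two anchors.
#' @return An object of class `genetic_map`.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "chr1",
#'                              pos = c(1, 1e6), cM = c(0, 1)))
#' interpolate_cM(gm, "chr1", 5e5)
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("chrom", "pos", "cM") %in% names(anchors)))
  anchors$chrom <- as.character(anchors$chrom)
  anchors <- anchors[order(anchors$chrom, anchors$pos), , drop = FALSE]
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, ]
    if (nrow(a) < 2) {
      stop("chromosome ", ch, " has fewer than 2 map anchors")
    }
    if (any(diff(a$pos) <= 0)) {
      stop("bp positions not strictly increasing on ", ch)
    }
    if (any(diff(a$cM) < 0)) {
      stop("cM positions not non-decreasing on ", ch)
    }
  }
  structure(list(anchors = anchors), class = "genetic_map")
}

#' Read a PLINK-style genetic map
#'
#' Accepts the four-column PLINK `.map` layout (chrom, id, cM, bp) or a
#' three-column (chrom, bp, cM) dialect, with or without a header.
#'
#' @param path Path to a whitespace- or tab-delimited map file.
#' @param format `"plink"` (chrom, id, cM, bp) or `"bp_cM"` (chrom, bp,
#'   cM).
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, format = c("plink", "bp_cM")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = "auto")
  if (format == "plink") {
    if (ncol(dt) < 4) stop("PLINK map needs 4 columns: chrom id cM bp")
    anchors <- data.frame(chrom = as.character(dt[[1]]),
                          pos = as.numeric(dt[[4]]),
                          cM = as.numeric(dt[[3]]))
  } else {
    if (ncol(dt) < 3) stop("bp_cM map needs 3 columns: chrom bp cM")
    anchors <- data.frame(chrom = as.character(dt[[1]]),
                          pos = as.numeric(dt[[2]]),
                          cM = as.numeric(dt[[3]]))
  }
  genetic_map(anchors)
}

#' Uniform genetic map at a constant recombination rate
#'
#' Convenience constructor for synthetic data: a map with one anchor at
#' each chromosome end and a constant rate of `rate` recombination
#' events per bp per generation (1e-8 corresponds to 1 cM/Mb).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in
#'   bp (names are chromosome ids).
#' @param rate Recombination rate per bp per generation.
#' @return A [genetic_map()].
#' @export
uniform_genetic_map <- function(chrom_lengths, rate = 1e-8) {
  stopifnot(!is.null(names(chrom_lengths)), rate > 0)
  anchors <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    data.frame(chrom = ch, pos = c(1, L),
               cM = c(0, (L - 1) * rate * 100))
  }))
  genetic_map(anchors)
}

#' @export
print.genetic_map <- function(x, ...) {
  ch <- unique(x$anchors$chrom)
  spans <- vapply(ch, function(c) {
    a <- x$anchors[x$anchors$chrom == c, ]
    max(a$cM) - min(a$cM)
  }, numeric(1))
  cat("genetic_map:", length(ch), "chromosome(s),",
      format(sum(spans), digits = 4), "cM total\n")
  invisible(x)
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between the two bracketing anchors; positions
#' outside the anchored range are clamped to the terminal anchor's cM.
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome id (single value).
#' @param bp Vector of physical positions (bp).
#' @return Numeric vector of genetic positions in cM.
#' @export
interpolate_cM <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"), length(chrom) == 1)
  a <- map$anchors[map$anchors$chrom == as.character(chrom), ]
  if (nrow(a) == 0) stop("unknown chromosome: ", chrom)
  stats::approx(a$pos, a$cM, xout = bp, rule = 2, ties = "ordered")$y
}

#' Genetic distance between two sites on the same chromosome
#'
#' @param map A [genetic_map()].
#' @param chrom_a,bp_a,chrom_b,bp_b Chromosome and physical position of
#'   the two sites.
#' @return Distance in cM (multiply by 10 for mM, divide by 100 for
#'   Morgans).
#' @export
genetic_distance <- function(map, chrom_a, bp_a, chrom_b, bp_b) {
  if (as.character(chrom_a) != as.character(chrom_b)) {
    stop("genetic_distance is defined within a chromosome only")
  }
  abs(interpolate_cM(map, chrom_a, bp_a) - interpolate_cM(map, chrom_b, bp_b))
}

#' Tile the mapped span of each chromosome into fixed genetic windows
#'
#' Windows are half-open intervals `[k*size, (k+1)*size)` in cM,
#' anchored at each chromosome's first mapped genetic position, so
#' every mapped site falls into exactly one window. The last window of
#' a chromosome may be shorter than `size_cM`; a chromosome span that
#' is an exact multiple of the window size produces exactly
#' `span / size_cM` windows.
#'
#' @param map A [genetic_map()].
#' @param size_cM Window size in cM (default 1).
#' @return A data.frame with columns `chrom`, `window` (index within
#'   chromosome), `start_cM`, `end_cM`, `start_bp`, `end_bp` (physical
#'   projections of the window bounds).
#' @export
make_windows <- function(map, size_cM = 1.0) {
  stopifnot(inherits(map, "genetic_map"), size_cM > 0)
  out <- lapply(unique(map$anchors$chrom), function(ch) {
    a <- map$anchors[map$anchors$chrom == ch, ]
    lo <- min(a$cM)
    hi <- max(a$cM)
    span <- hi - lo
    if (span <= 0) return(NULL)
    n <- ceiling(span / size_cM - 1e-9)
    starts <- lo + (seq_len(n) - 1) * size_cM
    ends <- pmin(starts + size_cM, hi)
    # physical projection: invert the piecewise-linear map
    bp_at <- function(cm) {
      stats::approx(a$cM, a$pos, xout = cm, rule = 2, ties = "ordered")$y
    }
    data.frame(chrom = ch, window = seq_len(n),
               start_cM = starts, end_cM = ends,
               start_bp = bp_at(starts), end_bp = bp_at(ends))
  })
  do.call(rbind, out)
}

#' Assign sites to genetic windows
#'
#' @param map A [genetic_map()].
#' @param windows Output of [make_windows()].
#' @param chrom,bp Site coordinates.
#' @return Integer vector: row index into `windows` for each site (the
#'   chromosome's last window for sites at the terminal map position).
#' @keywords internal
window_of <- function(map, windows, chrom, bp) {
  idx <- integer(length(bp))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    w <- which(windows$chrom == ch)
    if (length(w) == 0) stop("no windows for chromosome ", ch)
    cm <- interpolate_cM(map, ch, bp[sel])
    k <- findInterval(cm, windows$start_cM[w], rightmost.closed = FALSE)
    k[k < 1] <- 1L
    k[k > length(w)] <- length(w)
    idx[sel] <- w[k]
  }
  idx
}
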