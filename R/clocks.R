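#' Configuration for the generation-count clocks
#'
#' @param mu Mutation rate per bp per generation on the retained site
#'   class (for transversion panels, the transversion-rescaled rate;
#'   for synthetic data, the simulated rate).
#' @param masked_chromosomes Chromosomes excluded from the
#'   recombination clock (poorly mapped regions in real data; empty for
#'   synthetic data).
#' @param bin_edges_mM Distance-bin edges in milliMorgans, strictly
#'   increasing. The default, 48 log-spaced bins over 0.01-100 mM,
#'   resolves exponential decay rates between roughly 1e2 and 1e5
#'   generations.
#' @param max_pairs_per_bin Cap on pairs counted per bin (seeded
#'   hypergeometric thinning above the cap); `Inf` disables.
#' @param t_bounds Bounds (generations) for the per-sample `t_i`
#'   search.
#' @param bg_ridge Ridge penalty weight shrinking the shared
#'   background curve of the recombination-clock fit towards zero;
#'   breaks the trade-off between the background and the per-sample
#'   decay terms (see [fit_recombination_clock()]).
#' @param seed RNG seed (pair-count thinning).
#' @return An object of class `clock_config`.
#' @export
clock_config <- function(mu, masked_chromosomes = character(),
                         bin_edges_mM = NULL,
                         max_pairs_per_bin = 2e6,
                         t_bounds = c(100, 1e5),
                         bg_ridge = 0.2,
                         seed = 1L) {
  stopifnot(mu > 0)
  if (is.null(bin_edges_mM)) {
    bin_edges_mM <- exp(seq(log(0.01), log(100), length.out = 49))
  }
  stopifnot(all(diff(bin_edges_mM) > 0), all(bin_edges_mM > 0))
  structure(list(mu = mu,
                 masked_chromosomes = as.character(masked_chromosomes),
                 bin_edges_mM = bin_edges_mM,
                 max_pairs_per_bin = max_pairs_per_bin,
                 t_bounds = t_bounds,
                 bg_ridge = bg_ridge,
                 seed = as.integer(seed)),
            class = "clock_config")
}

# per-sample, per-chromosome derived counts (NA-aware)
derived_by_chrom <- function(x) {
  chroms <- unique(x$sites$chrom)
  out <- sapply(chroms, function(ch) {
    rowSums(x$calls[, x$sites$chrom == ch, drop = FALSE] == 1L,
            na.rm = TRUE)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(x$calls),
                                       dimnames = list(rownames(x$calls),
                                                       chroms))
  out
}

# callable length per sample x chromosome; apportioned by panel-site
# share when only a total is known
callable_by_chrom <- function(x) {
  chroms <- unique(x$sites$chrom)
  if (!is.null(x$chrom_callable)) {
    return(x$chrom_callable[, chroms, drop = FALSE])
  }
  if (is.null(x$callable_length)) stop("callable_length is not set")
  share <- table(factor(x$sites$chrom, levels = chroms))
  share <- as.numeric(share) / sum(share)
  outer(x$callable_length, share)
}

#' Mutation clock: generations since the ancestral sequence
#'
#' Converts each genome's derived-mutation density pi (derived calls
#' per callable bp, see [derived_fraction()]) into a generation count
#' `G = pi / mu`. Uncertainty is estimated by leave-one-chromosome-out
#' jackknife: `var = (m-1)/m * sum((G_(j) - mean(G_(j)))^2)` over the
#' `m` chromosomes.
#'
#' @param x A [site_matrix()] with callable lengths.
#' @param config A [clock_config()] (only `mu` is used).
#' @return data.frame with columns `sample`, `pi`, `G_mut`, `var_jk`.
#' @export
mutation_clock <- function(x, config) {
  stopifnot(inherits(x, "site_matrix"), inherits(config, "clock_config"))
  pi_i <- derived_fraction(x)
  D <- derived_by_chrom(x)
  C <- callable_by_chrom(x)
  m <- ncol(D)
  var_jk <- rep(NA_real_, nrow(D))
  if (m >= 2) {
    G_loco <- sapply(seq_len(m), function(j) {
      (rowSums(D) - D[, j]) / (rowSums(C) - C[, j]) / config$mu
    })
    var_jk <- (m - 1) / m * rowSums((G_loco - rowMeans(G_loco))^2)
  }
  data.frame(sample = rownames(x$calls), pi = unname(pi_i),
             G_mut = unname(pi_i) / config$mu, var_jk = unname(var_jk))
}

#' Derived-pair decay curve for one genome
#'
#' For every pair of panel sites on the same (unmasked) chromosome,
#' separated by genetic distance d, the statistic is the probability
#' that the genome carries the derived allele at both sites, binned on
#' d and normalized by the genome's derived-call rate over the same
#' panel (`pi_panel`, derived calls / called sites). The normalized
#' curve N(d) decays from an excess at short range -- where the two
#' derived alleles tend to descend together from the same ancestral
#' haplotype -- towards the no-linkage baseline `pi_panel` at long
#' range; the decay rate per Morgan measures generations of
#' recombination opportunity since the most recent common ancestor.
#'
#' @param x A [site_matrix()].
#' @param sample Sample id.
#' @param map A [genetic_map()] covering the matrix's chromosomes.
#' @param config A [clock_config()].
#' @return An object of class `pair_decay_curve`: list with `sample`,
#'   `pi_panel`, `bins` (data.frame: mid_mM, n_pairs, n_both, N) and
#'   `by_chrom` (3-d array bins x {pairs, both} x chromosome, the
#'   substrate of the leave-one-chromosome-out jackknife).
#' @export
pair_statistic <- function(x, sample, map, config) {
  stopifnot(inherits(x, "site_matrix"), inherits(map, "genetic_map"),
            inherits(config, "clock_config"))
  calls <- x$calls[sample, ]
  chroms <- setdiff(unique(x$sites$chrom), config$masked_chromosomes)
  if (length(chroms) == 0) stop("all chromosomes are masked")
  keep <- x$sites$chrom %in% chroms
  called <- !is.na(calls[keep])
  n_derived <- sum(calls[keep][called] == 1L)
  if (sum(called) < 2) stop("sample has fewer than 2 called sites")
  pi_panel <- n_derived / sum(called)
  edges <- config$bin_edges_mM
  nb <- length(edges) - 1
  by_chrom <- array(0, dim = c(nb, 2, length(chroms)),
                    dimnames = list(NULL, c("pairs", "both"), chroms))
  withr::with_seed(config$seed, {
    for (ch in chroms) {
      sel <- x$sites$chrom == ch
      if (sum(sel) < 2) next
      g <- interpolate_cM(map, ch, x$sites$pos[sel]) * 10  # cM -> mM
      cnt <- pair_bin_counts(calls[sel], g, edges)
      # pair counting is exact; a finite cap is honoured by
      # hypergeometric thinning of the per-bin counts
      over <- which(cnt[, 1] > config$max_pairs_per_bin)
      for (b in over) {
        m <- config$max_pairs_per_bin
        cnt[b, 2] <- stats::rhyper(1, cnt[b, 2], cnt[b, 1] - cnt[b, 2], m)
        cnt[b, 1] <- m
      }
      by_chrom[, , ch] <- cnt
    }
  })
  tot <- apply(by_chrom, c(1, 2), sum)
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  bins <- data.frame(mid_mM = mids, n_pairs = tot[, 1], n_both = tot[, 2],
                     N = ifelse(tot[, 1] > 0,
                                (tot[, 2] / tot[, 1]) / pi_panel, NA))
  if (n_derived == 0) {
    warning("sample ", sample, " has no derived calls; curve undefined")
  }
  structure(list(sample = sample, pi_panel = pi_panel, bins = bins,
                 by_chrom = by_chrom),
            class = "pair_decay_curve")
}

#' Pair-decay curves for many samples
#'
#' @param x A [site_matrix()].
#' @param map A [genetic_map()].
#' @param config A [clock_config()].
#' @param samples Sample ids (default all).
#' @return Named list of [pair_statistic()] curves.
#' @export
pair_statistics <- function(x, map, config, samples = rownames(x$calls)) {
  stats::setNames(lapply(samples, function(s)
    pair_statistic(x, s, map, config)), samples)
}

# ---- recombination-clock model ----------------------------------------
#
# N_i(d) = pi_i + c_i + a_{class(i)} exp(-d t_i) + g(d)
#
# with d in Morgans. The per-sample rate t_i is the recombination
# opportunity along the MRCA-to-sample path: a pair of derived alleles
# shows excess co-occurrence while no recombination has separated them
# on that path, an event of probability exp(-d t_i), so the decay rate
# carries the generation signal. Three nuisance structures make the
# per-genome fit identifiable and stable at small genome sizes:
#
#   * g(d), a background-association curve shared by every sample of
#     the panel, absorbs the slowly decaying correlation created by
#     lineages that recombine but re-coalesce within the population
#     (strong at small Ne) -- fitting it per sample would let it
#     swallow the decay signal, while omitting it biases t_i low;
#   * the amplitude is pooled within inbreeding classes (self-paired /
#     outbred): a per-sample free amplitude trades off against t_i and
#     roughly doubles the estimator noise, and the amplitude is a
#     nuisance here;
#   * a per-sample intercept c_i absorbs the finite-panel error of the
#     pi_i baseline (a ~1% relative error in pi_i otherwise leaks
#     directly into t_i).
#
# Estimation is cyclic weighted least squares: g, the class
# amplitudes, and each (t_i, c_i) are updated in turn; each t_i update
# is a 1-d log-grid search refined by golden-section. Weights are the
# square root of per-bin pair counts -- pair counts overstate the
# information in long-range bins, where neighbouring pairs are almost
# perfectly correlated through the shared genealogy, and the square
# root is an effective compromise between binomial weighting and that
# correlation. The classical per-sample amplitude is reported as
# p_i = a_i T / t_i with T chosen so the nuisance constants p_i
# concentrate around 1 (ridge argument).

# aggregate a curve into (y, w) over its bins; NA bins get weight 0
curve_yw <- function(curve, drop_chrom = NULL) {
  tot <- if (is.null(drop_chrom)) {
    apply(curve$by_chrom, c(1, 2), sum)
  } else {
    keep <- setdiff(dimnames(curve$by_chrom)[[3]], drop_chrom)
    apply(curve$by_chrom[, , keep, drop = FALSE], c(1, 2), sum)
  }
  ok <- tot[, 1] > 0
  y <- rep(0, nrow(tot))
  y[ok] <- (tot[ok, 2] / tot[ok, 1]) / curve$pi_panel - curve$pi_panel
  w <- numeric(nrow(tot))
  w[ok] <- sqrt(tot[ok, 1])
  cbind(y = y, w = w)
}

# per-sample update: 1-d search over t with the intercept profiled
fit_one_t <- function(y, w, dM, a, t_bounds, n_grid = 60) {
  sw <- sum(w)
  rss_at <- function(t) {
    e <- a * exp(-dM * t)
    cc <- sum(w * (y - e)) / sw
    sum(w * (y - e - cc)^2)
  }
  grid <- exp(seq(log(t_bounds[1]), log(t_bounds[2]), length.out = n_grid))
  vals <- vapply(grid, rss_at, numeric(1))
  k <- which.min(vals)
  opt <- stats::optimize(function(lt) rss_at(exp(lt)),
                         interval = c(log(grid[max(1, k - 1)]),
                                      log(grid[min(n_grid, k + 1)])),
                         tol = 1e-8)
  t_hat <- exp(opt$minimum)
  e <- a * exp(-dM * t_hat)
  c_hat <- sum(w * (y - e)) / sw
  list(t = t_hat, c = c_hat, rss = sum(w * (y - e - c_hat)^2))
}

#' Fit the recombination clock by least squares
#'
#' Joint weighted least-squares fit of the pair-decay model
#' `N_i(d) = pi_i + p_i (t_i/T) exp(-d t_i)` plus shared nuisance
#' structure to a set of per-sample decay curves: `t_i` is each
#' sample's generations of recombination opportunity since the MRCA
#' (the decay rate, which carries the signal), `T` the mean total
#' genealogical length and `p_i` a per-sample nuisance amplitude. The
#' exponential amplitude is pooled within inbreeding classes, a
#' background-association curve shared by all samples and a per-sample
#' baseline offset are estimated alongside (see the comment block in
#' the source for the rationale), and the amplitude/`T` trade-off is
#' resolved by a ridge argument pulling the `p_i` towards 1. Cyclic
#' descent stops when the relative change of the total RSS falls below
#' `tol`.
#'
#' @param curves List of [pair_statistic()] curves (one per sample).
#' @param config A [clock_config()].
#' @param init Optional data.frame with columns `sample` and `G_mut`
#'   (e.g. from [mutation_clock()]) used to initialize the `t_i`
#'   search.
#' @param classes Optional factor/character vector (named by sample or
#'   aligned with `curves`) assigning each sample to an amplitude
#'   class, typically `"self"` for fully inbred (self-paired) genomes
#'   and `"outbred"` otherwise; one class for all samples by default.
#' @param tol Relative RSS convergence tolerance.
#' @param max_iter Maximum descent cycles.
#' @return An object of class `rec_clock_fit`: data.frame `estimates`
#'   (sample, pi_panel, class, t_i, p_i, offset, rss), `T`,
#'   `amplitudes` (per class), `background` (shared curve over bins),
#'   `rss`, `converged`.
#' @export
fit_recombination_clock <- function(curves, config, init = NULL,
                                    classes = NULL, tol = 1e-6,
                                    max_iter = 100) {
  stopifnot(length(curves) >= 1, inherits(config, "clock_config"))
  ns <- length(curves)
  samples <- names(curves)
  if (is.null(samples)) samples <- vapply(curves, `[[`, "", "sample")
  yw <- lapply(curves, curve_yw)
  Y <- sapply(yw, function(m) m[, "y"])
  W <- sapply(yw, function(m) m[, "w"])
  usable <- colSums(W > 0) >= 3
  if (!any(usable)) stop("no usable decay curves")
  if (!all(usable)) {
    warning("curves without usable bins: ",
            paste(samples[!usable], collapse = ", "))
    Y <- Y[, usable, drop = FALSE]; W <- W[, usable, drop = FALSE]
    curves <- curves[usable]; samples <- samples[usable]
    ns <- length(curves)
  }
  if (is.null(classes)) {
    classes <- rep("all", ns)
  } else {
    if (!is.null(names(classes))) classes <- classes[samples]
    classes <- as.character(classes)
    stopifnot(length(classes) == ns, !anyNA(classes))
  }
  mids <- curves[[1]]$bins$mid_mM
  dM <- mids / 1000
  tb <- config$t_bounds
  t_i <- rep(exp(mean(log(tb))), ns)
  if (!is.null(init) && all(c("sample", "G_mut") %in% names(init))) {
    m <- match(samples, init$sample)
    ok <- !is.na(m) & init$G_mut[m] > 0
    t_i[ok] <- pmin(pmax(init$G_mut[m][ok], tb[1]), tb[2])
  }
  c_i <- numeric(ns)
  cls_levels <- unique(classes)
  a_cl <- stats::setNames(rep(0.05, length(cls_levels)), cls_levels)
  g <- numeric(length(dM))
  wsum <- rowSums(W)
  alpha <- config$bg_ridge
  rss <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E <- sapply(seq_len(ns), function(i) exp(-dM * t_i[i]))
    # shared background: ridge-shrunk weighted mean residual. The
    # shrinkage (penalty alpha * sum w g^2) gives the over-complete
    # model a unique optimum: with g fully free, g and the per-sample
    # exponentials trade off along a near-flat ridge and the t_i drift
    # collectively.
    R <- Y - sweep(E, 2, a_cl[classes], "*") -
      matrix(c_i, length(dM), ns, byrow = TRUE)
    g <- ifelse(wsum > 0, rowSums(W * R) / (wsum * (1 + alpha)), 0)
    g <- g - stats::weighted.mean(g, wsum)
    # class amplitudes (non-negative)
    for (cl in cls_levels) {
      idx <- which(classes == cl)
      num <- sum(W[, idx] * (Y[, idx] - g - rep(c_i[idx],
                                                each = length(dM))) *
                   E[, idx])
      den <- sum(W[, idx] * E[, idx]^2)
      if (den > 0) a_cl[cl] <- max(num / den, 1e-8)
    }
    # per-sample decay rates and offsets
    new_rss <- alpha * sum(wsum * g^2)
    for (i in seq_len(ns)) {
      f <- fit_one_t(Y[, i] - g, W[, i], dM, a_cl[classes[i]], tb)
      t_i[i] <- f$t; c_i[i] <- f$c
      new_rss <- new_rss + f$rss
    }
    # absolute floor keeps machine-noise oscillation of a perfect fit
    # from masking convergence
    rss_floor <- 1e-10 * max(sum(W * Y^2), .Machine$double.eps)
    if (is.finite(rss) &&
        (new_rss <= rss_floor || abs(rss - new_rss) <= tol * rss)) {
      rss <- new_rss
      converged <- TRUE
      break
    }
    rss <- new_rss
  }
  # ridge argument: T minimizing sum (a_i T / t_i - 1)^2
  a_i <- unname(a_cl[classes])
  r <- a_i / t_i
  T_hat <- if (sum(r^2) > 0) sum(r) / sum(r^2) else NA_real_
  p_i <- r * T_hat
  est <- data.frame(
    sample = samples,
    pi_panel = vapply(curves, `[[`, 0, "pi_panel"),
    class = classes,
    t_i = t_i, p_i = p_i, offset = c_i,
    rss = vapply(seq_len(ns), function(i) {
      e <- a_i[i] * exp(-dM * t_i[i])
      sum(W[, i] * (Y[, i] - g - c_i[i] - e)^2)
    }, numeric(1)),
    row.names = NULL)
  structure(list(estimates = est, T = T_hat, amplitudes = a_cl,
                 background = data.frame(mid_mM = mids, g = g),
                 rss = rss, converged = converged, config = config),
            class = "rec_clock_fit")
}

#' @export
print.rec_clock_fit <- function(x, ...) {
  cat("rec_clock_fit:", nrow(x$estimates), "samples | T =",
      format(x$T, digits = 5), "| converged:", x$converged, "\n")
  cat("  amplitudes:", paste(names(x$amplitudes),
                             format(x$amplitudes, digits = 3),
                             sep = "=", collapse = " "), "\n")
  cat("  t_i range:",
      paste(format(range(x$estimates$t_i), digits = 5), collapse = " - "),
      "generations\n")
  invisible(x)
}

#' Leave-one-chromosome-out jackknife for the recombination clock
#'
#' Refits each sample's `t_i` with one chromosome's pairs removed at a
#' time -- the shared background curve and class amplitudes are held at
#' their full-data values -- and returns the jackknife variance
#' `(m-1)/m * sum((t_(j) - mean(t_(j)))^2)` over the `m` unmasked
#' chromosomes.
#'
#' @param curves List of [pair_statistic()] curves.
#' @param fit The full-data [fit_recombination_clock()] result.
#' @return data.frame with `sample`, `t_i`, `var_jk`.
#' @export
jackknife_recclock <- function(curves, fit) {
  stopifnot(inherits(fit, "rec_clock_fit"))
  config <- fit$config
  est <- fit$estimates
  g <- fit$background$g
  dM <- fit$background$mid_mM / 1000
  out <- lapply(seq_len(nrow(est)), function(k) {
    s <- est$sample[k]
    curve <- curves[[s]]
    a <- unname(fit$amplitudes[est$class[k]])
    chroms <- dimnames(curve$by_chrom)[[3]]
    m <- length(chroms)
    if (m < 2) stop("jackknife needs at least 2 unmasked chromosomes")
    t_loco <- vapply(chroms, function(ch) {
      yw <- curve_yw(curve, drop_chrom = ch)
      if (sum(yw[, "w"] > 0) < 3) return(NA_real_)
      fit_one_t(yw[, "y"] - g, yw[, "w"], dM, a, config$t_bounds)$t
    }, numeric(1))
    t_loco <- t_loco[!is.na(t_loco)]
    m_eff <- length(t_loco)
    var_jk <- if (m_eff >= 2) {
      (m_eff - 1) / m_eff * sum((t_loco - mean(t_loco))^2)
    } else NA_real_
    data.frame(sample = s, t_i = est$t_i[k], var_jk = var_jk)
  })
  do.call(rbind, out)
}

#' Run both clocks on a site matrix
#'
#' Convenience wrapper: mutation clock, per-sample pair-decay curves,
#' recombination-clock fit and its jackknife, merged into one table.
#'
#' @param x A [site_matrix()].
#' @param map A [genetic_map()].
#' @param config A [clock_config()].
#' @param jackknife Compute leave-one-chromosome-out variances.
#' @return A list with `table` (per-sample data.frame: sample, pi,
#'   G_mut, var_jk_mut, pi_panel, t_i, p_i, var_jk_rec), `fit` (the
#'   [fit_recombination_clock()] object) and `curves`.
#' @export
run_clocks <- function(x, map, config, jackknife = TRUE) {
  mc <- mutation_clock(x, config)
  curves <- pair_statistics(x, map, config)
  classes <- NULL
  if (!is.null(x$samples$self_paired)) {
    classes <- stats::setNames(
      ifelse(x$samples$self_paired, "self", "outbred"), x$samples$sample)
  }
  fit <- fit_recombination_clock(curves, config, init = mc,
                                 classes = classes)
  tab <- merge(stats::setNames(mc, c("sample", "pi", "G_mut", "var_jk_mut")),
               fit$estimates[, c("sample", "pi_panel", "t_i", "p_i")],
               by = "sample", sort = FALSE)
  if (jackknife) {
    jk <- jackknife_recclock(curves, fit)
    tab <- merge(tab, stats::setNames(jk[, c("sample", "var_jk")],
                                      c("sample", "var_jk_rec")),
                 by = "sample", sort = FALSE)
  }
  list(table = tab, fit = fit, curves = curves)
}
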