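#' Penalized-spline trend of generation counts on calendar date
#'
#' Regresses per-sample generation counts (typically the
#' recombination-clock t_i) on calendar date through a penalized cubic
#' regression spline, with optional linear covariates capturing
#' population structure and sequencing depth, and inverse-variance
#' weights from the leave-one-chromosome-out jackknife. The same data
#' are also fitted with a linear date term, and the two models are
#' compared by an F test: on data where generations accumulate at a
#' constant rate the penalty shrinks the spline to the line and the
#' test is non-significant, while changes in generation time bend the
#' spline and reject linearity.
#'
#' Sign conventions: dates are signed calendar years increasing towards
#' the present (BCE years are negative); generation counts since the
#' MRCA also increase towards the present, so the expected derivative
#' is positive and its reciprocal is the generation time in years.
#'
#' @param data data.frame with columns `sample`, `t` (generation
#'   count), `date` (signed calendar year), `weight` (inverse
#'   jackknife variance; positive), plus any covariate columns.
#' @param covariates Character vector naming covariate columns of
#'   `data` entering linearly (e.g. structure coordinates, depth
#'   proxy); may be empty.
#' @param k Spline basis dimension (default 20).
#' @param select_by Smoothing-parameter selection: `"REML"` (default)
#'   or `"GCV.Cp"`.
#' @return An object of class `trend_fit`: list with `gam` and
#'   `linear` (mgcv fits), `anova` (F comparison), `adj_r2` (named
#'   vector), `data`, `covariates`.
#' @export
fit_generation_trend <- function(data, covariates = character(),
                                 k = 20, select_by = c("REML", "GCV.Cp")) {
  select_by <- match.arg(select_by)
  stopifnot(all(c("t", "date", "weight") %in% names(data)),
            all(covariates %in% names(data)))
  if (any(!is.finite(data$weight)) || any(data$weight <= 0)) {
    stop("weights must be positive and finite")
  }
  if (nrow(data) < k + length(covariates) + 1) {
    stop("fewer samples than model coefficients; lower k")
  }
  if (length(covariates)) {
    X <- as.matrix(data[, covariates, drop = FALSE])
    qrX <- qr(cbind(1, data$date, X))
    if (qrX$rank < ncol(X) + 2) {
      bad <- setdiff(c("date", covariates),
                     c("date", covariates)[qrX$pivot[seq_len(qrX$rank)] - 1])
      stop("collinear covariate column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  cov_terms <- if (length(covariates)) {
    paste("+", paste(covariates, collapse = " + "))
  } else ""
  f_gam <- stats::as.formula(
    paste0("t ~ s(date, bs = 'cr', k = ", k, ")", cov_terms))
  f_lin <- stats::as.formula(paste0("t ~ date", cov_terms))
  m_gam <- mgcv::gam(f_gam, data = data, weights = data$weight,
                     method = select_by)
  m_lin <- mgcv::gam(f_lin, data = data, weights = data$weight,
                     method = select_by)
  an <- stats::anova(m_lin, m_gam, test = "F")
  adj_r2 <- c(linear = summary(m_lin)$r.sq, gam = summary(m_gam)$r.sq)
  structure(list(gam = m_gam, linear = m_lin, anova = an,
                 adj_r2 = adj_r2, data = data, covariates = covariates,
                 k = k),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  p <- x$anova[2, "Pr(>F)"]
  cat("trend_fit:", nrow(x$data), "samples | adj R2 linear",
      sprintf("%.3f", x$adj_r2["linear"]), "vs spline",
      sprintf("%.3f", x$adj_r2["gam"]),
      "| linearity F-test p =", format.pval(p, digits = 3), "\n")
  invisible(x)
}

# spline derivative with delta-method band, by finite differences on
# the linear-predictor matrix (covariates held at their means)
trend_derivative <- function(fit, dates, eps = 1, level = 0.95) {
  nd <- data.frame(date = dates)
  for (cv in fit$covariates) nd[[cv]] <- mean(fit$data[[cv]])
  nd_hi <- nd_lo <- nd
  nd_hi$date <- nd$date + eps / 2
  nd_lo$date <- nd$date - eps / 2
  Xd <- (stats::predict(fit$gam, nd_hi, type = "lpmatrix") -
           stats::predict(fit$gam, nd_lo, type = "lpmatrix")) / eps
  beta <- stats::coef(fit$gam)
  V <- stats::vcov(fit$gam)
  deriv <- drop(Xd %*% beta)
  se <- sqrt(rowSums((Xd %*% V) * Xd))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(date = dates, deriv = deriv,
             lo = deriv - z * se, hi = deriv + z * se)
}

#' Generation-time profile in calendar-time bins
#'
#' Evaluates the fitted trend's date-derivative (generations per year)
#' on a fine grid, averages it within fixed calendar bins, and inverts
#' it into years per generation with a delta-method confidence band. A
#' bin whose derivative is not credibly positive (the interval reaches
#' zero or below) gets `NA` generation time rather than a meaningless
#' inversion.
#'
#' @param fit A [fit_generation_trend()] result.
#' @param bin_years Bin width in calendar years (default 1000).
#' @param level Confidence level for the band.
#' @param grid_step Grid spacing in years for derivative evaluation.
#' @return data.frame: `bin_start`, `bin_end` (signed years),
#'   `deriv` (gen/year), `gen_time` (years/generation), `lo95`, `hi95`
#'   (band for `gen_time`).
#' @export
generation_time_profile <- function(fit, bin_years = 1000, level = 0.95,
                                    grid_step = 10) {
  stopifnot(inherits(fit, "trend_fit"), bin_years > 0)
  r <- range(fit$data$date)
  lo <- floor(r[1] / bin_years) * bin_years
  hi <- ceiling(r[2] / bin_years) * bin_years
  grid <- seq(lo + grid_step / 2, hi - grid_step / 2, by = grid_step)
  d <- trend_derivative(fit, grid, level = level)
  bin <- floor(grid / bin_years) * bin_years
  agg <- function(v) tapply(v, bin, mean)
  deriv <- agg(d$deriv); dlo <- agg(d$lo); dhi <- agg(d$hi)
  starts <- as.numeric(names(deriv))
  pos <- dlo > 0  # credibly positive derivative required to invert
  data.frame(bin_start = starts, bin_end = starts + bin_years,
             deriv = unname(deriv),
             gen_time = unname(ifelse(pos, 1 / deriv, NA)),
             lo95 = unname(ifelse(pos, 1 / dhi, NA)),
             hi95 = unname(ifelse(pos, 1 / dlo, NA)),
             row.names = NULL)
}

#' Long-term average generation time over a calendar window
#'
#' The inverse of the weighted linear slope of generation counts on
#' date over the most recent `window_years` of the data: the average
#' number of calendar years per generation across that window.
#'
#' @param data As in [fit_generation_trend()].
#' @param covariates Covariate columns entering the linear fit.
#' @param window_years Window, counted back from the most recent
#'   sample (default 15000).
#' @return A list with `gen_time` (years), `slope` (gen/year), `se`
#'   (delta-method standard error of `gen_time`) and `n`.
#' @export
long_term_generation_time <- function(data, covariates = character(),
                                      window_years = 15000) {
  stopifnot(all(c("t", "date", "weight") %in% names(data)))
  sel <- data$date >= max(data$date) - window_years
  d <- data[sel, , drop = FALSE]
  if (nrow(d) < 2) stop("fewer than 2 samples in the window")
  if (diff(range(d$date)) == 0) stop("all dates identical in the window")
  f <- stats::as.formula(
    paste(c("t ~ date", covariates), collapse = " + "))
  m <- stats::lm(f, data = d, weights = d$weight)
  slope <- stats::coef(m)["date"]
  se_slope <- summary(m)$coefficients["date", "Std. Error"]
  if (slope <= 0) {
    warning("non-positive slope; generation time undefined")
    return(list(gen_time = NA_real_, slope = unname(slope),
                se = NA_real_, n = nrow(d)))
  }
  list(gen_time = unname(1 / slope), slope = unname(slope),
       se = unname(se_slope / slope^2), n = nrow(d))
}
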