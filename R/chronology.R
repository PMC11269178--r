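#' Project a calendar date backwards by a number of generations
#'
#' Converts a generation count into calendar years and projects an
#' anchor date (in years BCE) further into the past. This is the
#' arithmetic used to place demographic events, expressed on a
#' generation axis, onto the calendar: an event `n_generations` before
#' an anchor at `anchor_bce` happened at
#' `anchor_bce + n_generations * gen_time_years` BCE.
#'
#' @param anchor_bce Anchor date, in years BCE (positive number; e.g.
#'   `1864` for 1864 BCE).
#' @param n_generations Number of generations before the anchor
#'   (non-negative).
#' @param gen_time_years Average generation time in years (> 0).
#' @return The projected date in years BCE, rounded to the nearest
#'   year.
#' @examples
#' date_before(3500, 80, 8)   # 4140 BCE
#' date_before(1864, 100, 12) # 3064 BCE
#' @seealso [generations_between()] for the inverse operation.
#' @export
date_before <- function(anchor_bce, n_generations, gen_time_years) {
  if (any(n_generations < 0)) {
    stop("n_generations must be non-negative")
  }
  if (any(gen_time_years <= 0)) {
    stop("gen_time_years must be positive")
  }
  round(anchor_bce + n_generations * gen_time_years)
}

#' Number of generations separating two calendar dates
#'
#' @param date_a_bce,date_b_bce Dates in years BCE.
#' @param gen_time_years Average generation time in years (> 0).
#' @return `|date_a_bce - date_b_bce| / gen_time_years`, unrounded.
#' @examples
#' generations_between(2664, 1864, 8) # 100
#' @export
generations_between <- function(date_a_bce, date_b_bce, gen_time_years) {
  if (any(gen_time_years <= 0)) {
    stop("gen_time_years must be positive")
  }
  abs(date_a_bce - date_b_bce) / gen_time_years
}

#' Generation time implied by a fold-acceleration
#'
#' An x-fold acceleration of reproduction relative to a long-term
#' average generation time shortens the generation interval to
#' `average / fold`.
#'
#' @param average_years Long-term average generation time in years.
#' @param fold_change Fold-acceleration (> 0); values above 1 shorten
#'   the generation time.
#' @return Generation time in years, rounded to one decimal place.
#' @examples
#' gen_time_from_fold(7.4, 2.1) # 3.5
#' @export
gen_time_from_fold <- function(average_years, fold_change) {
  if (any(fold_change <= 0)) {
    stop("fold_change must be positive")
  }
  round(average_years / fold_change, 1)
}

#' Convert calibrated years before present to years BCE
#'
#' Calibrated radiocarbon ages are conventionally expressed relative to
#' 1950 CE ("before present"). Continuous-year arithmetic is used
#' throughout (no year-zero gap).
#'
#' @param calbp Calibrated years before present (before 1950 CE).
#' @return Years BCE (negative values are CE dates).
#' @examples
#' calbp_to_bce(5450) # 3500 BCE
#' @export
calbp_to_bce <- function(calbp) {
  calbp - 1950
}
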