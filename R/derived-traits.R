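#' Grain sink filling rate
#'
#' Ratio of grain yield to the length of the grain-filling period (days from
#' 50\% flowering to seed maturity), converted to kg per hectare per day.
#'
#' @param grain_yield grain yield in t/ha (non-negative).
#' @param days_to_flowering days to 50\% flowering.
#' @param days_to_maturity days to seed maturity; must exceed
#'   `days_to_flowering`.
#' @return Grain sink filling rate in kg ha^-1 day^-1.
#' @examples
#' derive_gsfr(2.0, 60, 100)   # 50 kg/ha/day
#' @export
derive_gsfr <- function(grain_yield, days_to_flowering, days_to_maturity) {
  if (any(grain_yield < 0))
    stop("`grain_yield` must be non-negative", call. = FALSE)
  period <- derive_gfp(days_to_flowering, days_to_maturity)
  grain_yield * 1000 / period
}

#' Grain filling period
#'
#' Number of days between 50\% flowering and grain maturity.
#'
#' @inheritParams derive_gsfr
#' @return Grain filling period in days (strictly positive).
#' @export
derive_gfp <- function(days_to_flowering, days_to_maturity) {
  period <- days_to_maturity - days_to_flowering
  if (any(period <= 0))
    stop("grain filling period must be positive (days_to_maturity > days_to_flowering)",
         call. = FALSE)
  period
}
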