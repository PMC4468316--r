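#' Whole-body sweat rate from a local rate
#'
#' Extrapolates a ventilated-capsule local sweat rate (per cm^2 of skin) to the
#' whole body by multiplying by body surface area in cm^2.
#'
#' @param lsr Local sweat rate, mg·cm^-2·min^-1.
#' @param bsa_m2 Body surface area, m^2.
#' @return Whole-body sweat rate, mg·min^-1 (`lsr * bsa * 1e4`).
#' @export
whole_body_rate <- function(lsr, bsa_m2) {
  if (any(lsr < 0) || any(bsa_m2 <= 0)) {
    stop("whole_body_rate(): lsr must be >= 0 and bsa > 0", call. = FALSE)
  }
  lsr * bsa_m2 * 1e4
}

#' Normalize a per-minute sweat series by a sweat-inducing factor
#'
#' Elementwise ratio of a sweat series to a per-minute denominator (external
#' workload, heat production, or cumulative temperature-increment load).
#' Minutes where the denominator is at or below `eps` are masked rather than
#' divided: at exercise onset the workload and temperature load start near
#' zero and the ratio diverges.
#'
#' @param series Tibble with `minute` and `value` columns (the sweat rate).
#' @param denom Tibble with `minute` and `value` columns (the factor); must
#'   cover exactly the same minutes.
#' @param eps Masking threshold in denominator units (default 1e-6).
#' @param label Denominator label recorded in the output.
#' @return A tibble with `minute`, `value` (ratio, `NA` where masked),
#'   `masked` and `denominator`.
#' @export
normalize_sweat <- function(series, denom, eps = 1e-6, label = "denom") {
  stopifnot(all(c("minute", "value") %in% names(series)),
            all(c("minute", "value") %in% names(denom)))
  if (!identical(sort(series$minute), sort(denom$minute))) {
    stop("alignment error: series and denominator minutes differ", call. = FALSE)
  }
  d <- denom$value[match(series$minute, denom$minute)]
  masked <- !(d > eps)
  tibble::tibble(minute = series$minute,
                 value = ifelse(masked, NA_real_, series$value / d),
                 masked = masked,
                 denominator = label)
}

#' Per-minute increments of a series
#'
#' Difference from the previous minute. The first exercise minute's increment
#' uses the minute-0 baseline when one is supplied, and is undefined (`NA`)
#' otherwise.
#'
#' @param series Tibble with `minute` and `value`; minutes must be consecutive.
#' @param baseline Optional minute-0 value.
#' @return Tibble with `minute` and `increment` for every minute in `series`.
#' @export
per_minute_increment <- function(series, baseline = NULL) {
  stopifnot(all(c("minute", "value") %in% names(series)))
  s <- series[order(series$minute), , drop = FALSE]
  if (nrow(s) < 2 && is.null(baseline)) {
    stop("per_minute_increment(): need >= 2 minutes or a baseline", call. = FALSE)
  }
  if (any(diff(s$minute) != 1)) {
    stop("per_minute_increment(): minutes must be consecutive", call. = FALSE)
  }
  first <- if (is.null(baseline)) NA_real_ else s$value[1] - baseline
  tibble::tibble(minute = s$minute,
                 increment = c(first, diff(s$value)))
}
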