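#' Physical constants of the energetics model
#'
#' `kcal_watt_min` converts kilocalories to Watt·min (4186.8 J over 60 s =
#' 69.78): one kilocalorie of retained heat raises one kilogram of body water
#' by 1 degree C. `workload_divisor` converts vertical displacement in
#' kg·m·min^-1 to Watt·min (60/g = 6.118, conventionally printed 6.12, the
#' value used here).
#'
#' @return Named list of the two constants.
#' @export
energy_constants <- function() {
  list(kcal_watt_min = 69.78, workload_divisor = 6.12)
}

#' Default Bruce treadmill protocol
#'
#' Standard 3-minute stages of increasing speed and grade; speeds converted
#' from mph at 26.8224 m·min^-1 per mph.
#'
#' @return A tibble with `stage`, `speed_m_min`, `grade` (fraction) and
#'   `duration_min`.
#' @export
bruce_protocol <- function() {
  tibble::tibble(
    stage = 1:7,
    speed_m_min = c(1.7, 2.5, 3.4, 4.2, 5.0, 5.5, 6.0) * 26.8224,
    grade = c(0.10, 0.12, 0.14, 0.16, 0.18, 0.20, 0.22),
    duration_min = 3
  )
}

#' Protocol stage active during a given exercise minute
#'
#' @param minute Integer exercise minute (1-based).
#' @param protocol A protocol schedule as from [bruce_protocol()].
#' @return Integer vector of stage indices.
#' @export
stage_for_minute <- function(minute, protocol = bruce_protocol()) {
  ends <- cumsum(protocol$duration_min)
  idx <- findInterval(minute - 1e-9, c(0, ends)) # minute m in stage whose end >= m
  if (any(minute < 1) || any(idx > nrow(protocol))) {
    stop("schedule-exhausted error: exercise minute beyond protocol schedule",
         call. = FALSE)
  }
  idx
}

#' Vertical displacement on an inclined treadmill
#'
#' Work against gravity per minute: grade (as a fraction) times belt speed
#' (m·min^-1) times body weight (kg).
#'
#' @param grade Treadmill grade as a fraction (0.10 = 10%).
#' @param speed_m_min Belt speed in metres per minute.
#' @param weight_kg Body weight in kg.
#' @return Vertical displacement in kg·m·min^-1.
#' @export
vertical_displacement <- function(grade, speed_m_min, weight_kg) {
  if (any(grade < 0) || any(speed_m_min < 0) || any(weight_kg <= 0)) {
    stop("vertical_displacement(): grade/speed must be >= 0 and weight > 0",
         call. = FALSE)
  }
  grade * speed_m_min * weight_kg
}

#' External workload from vertical displacement
#'
#' @param vd Vertical displacement in kg·m·min^-1.
#' @return External workload in Watt·min (vd / 6.12).
#' @export
external_workload <- function(vd) {
  if (any(vd < 0)) stop("external_workload(): vd must be >= 0", call. = FALSE)
  vd / energy_constants()$workload_divisor
}

#' Metabolic energy expenditure from oxygen uptake and respiratory quotient
#'
#' Indirect-calorimetry estimate of chemical energy liberated within a minute:
#' the energy equivalent of oxygen interpolates between the fat-only
#' (RQ = 0.7, 19.62 kJ·L^-1) and carbohydrate-only (RQ = 1.0, 21.13 kJ·L^-1)
#' limits, scaled by 16.67 to Watt·min:
#' `vo2 * (((rq - 0.7)/0.3) * 21.13 + ((1 - rq)/0.3) * 19.62) * 16.67`.
#'
#' Near exhaustion RQ can exceed 1 (hyperventilation CO2); by default it is
#' clamped to `[0.7, 1.0]` before evaluation, the physiologic convention, so
#' the substrate interpolation stays inside its calibration range. Set
#' `clamp_rq = FALSE` to extrapolate raw values for sensitivity analysis.
#'
#' @param vo2_L Litres of oxygen consumed within the minute (numerically the
#'   L·min^-1 rate over one minute).
#' @param rq Respiratory quotient.
#' @param clamp_rq Clamp RQ into `[0.7, 1.0]` first (default TRUE).
#' @return Metabolic energy expenditure in Watt·min.
#' @export
metabolic_energy <- function(vo2_L, rq, clamp_rq = TRUE) {
  if (any(vo2_L < 0)) stop("metabolic_energy(): vo2 must be >= 0", call. = FALSE)
  if (clamp_rq) rq <- pmin(pmax(rq, 0.7), 1.0)
  vo2_L * (((rq - 0.7) / 0.3) * 21.13 + ((1 - rq) / 0.3) * 19.62) * 16.67
}

#' Metabolic heat production
#'
#' Energy not converted to external work is released as heat. A negative
#' result (efficiency over 100%) is physically implausible but returned as-is
#' with a warning, so upstream data problems stay visible.
#'
#' @param m_ee,w_e Metabolic energy expenditure and external workload, Watt·min.
#' @return Heat production in Watt·min.
#' @export
heat_production <- function(m_ee, w_e) {
  if (any(m_ee < 0) || any(w_e < 0)) {
    stop("heat_production(): inputs must be >= 0", call. = FALSE)
  }
  h <- m_ee - w_e
  if (any(h < 0)) warning("heat_production(): efficiency over 100% (W_e > M_ee)")
  h
}

#' Metabolic efficiency
#'
#' @param w_e,m_ee External workload and metabolic energy expenditure, Watt·min.
#' @return Efficiency in percent; `NA` where `m_ee` is 0 (undefined).
#' @export
metabolic_efficiency <- function(w_e, m_ee) {
  out <- ifelse(m_ee > 0, 100 * w_e / m_ee, NA_real_)
  out
}

#' Temperature-increment load for one minute
#'
#' Heat produced beyond resting expenditure, expressed as the temperature rise
#' of total body water it would cause: 69.78 Watt·min (one kilocalorie) raises
#' one kg of body water by 1 degree C. Negative increments can arise in the
#' first instants of exercise; by default they are floored at 0 so the
#' cumulative value keeps its heat-load interpretation.
#'
#' @param h_prod Heat production for the minute, Watt·min.
#' @param m_ee_rest Resting metabolic energy expenditure per minute, Watt·min.
#' @param body_water_kg Total body water, kg.
#' @param floor_at_zero Floor negative increments at zero (default TRUE).
#' @return Temperature increment for the minute, degrees C.
#' @export
temperature_increment <- function(h_prod, m_ee_rest, body_water_kg,
                                  floor_at_zero = TRUE) {
  if (any(body_water_kg <= 0)) {
    stop("temperature_increment(): body water must be > 0", call. = FALSE)
  }
  t_inc <- (h_prod - m_ee_rest) / (energy_constants()$kcal_watt_min * body_water_kg)
  if (floor_at_zero) t_inc <- pmax(t_inc, 0)
  t_inc
}

#' Per-minute energetics series for one subject
#'
#' Combines the per-minute breath series (which must include the minute-0
#' resting record) with the treadmill protocol: external workload from the
#' stage active in each minute, metabolic energy from VO2/RQ, heat production,
#' efficiency, and the per-minute and cumulative temperature-increment load.
#' The cumulative reading of the temperature increment is used because the
#' minute increments are additive contributions to the same stored-heat pool.
#'
#' @param breath_minutes Per-minute tibble with `minute` (0 = resting), `vo2`
#'   (L·min^-1) and `rq`.
#' @param protocol Protocol schedule, see [bruce_protocol()].
#' @param weight_kg Body weight, kg.
#' @param body_water_kg Total body water, kg.
#' @param clamp_rq,floor_tinc Numerical-convention switches, see
#'   [metabolic_energy()] and [temperature_increment()].
#' @return A list with `minutes` (tibble: minute, w_e, m_ee, h_prod,
#'   efficiency_pct, t_inc_step, t_inc_cum), `totals` (one-row tibble) and
#'   `m_ee_rest`.
#' @export
build_energetics_series <- function(breath_minutes, protocol = bruce_protocol(),
                                    weight_kg, body_water_kg,
                                    clamp_rq = TRUE, floor_tinc = TRUE) {
  stopifnot(all(c("minute", "vo2", "rq") %in% names(breath_minutes)))
  if (!0L %in% breath_minutes$minute) {
    stop("minute-0 resting record required to define resting expenditure",
         call. = FALSE)
  }
  rest <- breath_minutes[breath_minutes$minute == 0L, ]
  m_ee_rest <- metabolic_energy(rest$vo2, rest$rq, clamp_rq = clamp_rq)
  ex <- breath_minutes[breath_minutes$minute >= 1L, , drop = FALSE]
  ex <- ex[order(ex$minute), , drop = FALSE]
  st <- stage_for_minute(ex$minute, protocol)
  vd <- vertical_displacement(protocol$grade[st], protocol$speed_m_min[st],
                              weight_kg)
  w_e <- external_workload(vd)
  m_ee <- metabolic_energy(ex$vo2, ex$rq, clamp_rq = clamp_rq)
  h_prod <- heat_production(m_ee, w_e)
  eff <- metabolic_efficiency(w_e, m_ee)
  t_step <- temperature_increment(h_prod, m_ee_rest, body_water_kg,
                                  floor_at_zero = floor_tinc)
  minutes <- tibble::tibble(
    minute = ex$minute, w_e = w_e, m_ee = m_ee, h_prod = h_prod,
    efficiency_pct = eff, t_inc_step = t_step, t_inc_cum = cumsum(t_step)
  )
  totals <- tibble::tibble(
    total_w_e = sum(w_e), total_m_ee = sum(m_ee), total_h_prod = sum(h_prod),
    mean_efficiency = ifelse(sum(m_ee) > 0, 100 * sum(w_e) / sum(m_ee), NA_real_),
    exercise_minutes = nrow(ex)
  )
  list(minutes = minutes, totals = totals, m_ee_rest = m_ee_rest)
}
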