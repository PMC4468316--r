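#' Column-mapping dialect for calorimeter exports
#'
#' Breath-by-breath calorimeter vendors export delimited text with varying
#' column names and units; the dialect maps them onto the fields the pipeline
#' needs. Time is in seconds from exercise start (negative values are the
#' pre-exercise resting segment).
#'
#' @param col_time,col_vo2,col_rq Column names in the export.
#' @param vo2_unit Either `"L_per_min"` or `"mL_per_min"`; mL values are
#'   converted on read.
#' @param delim Field delimiter.
#' @return A dialect object (list) accepted by [read_breath_trace()].
#' @export
breath_dialect <- function(col_time = "t_s", col_vo2 = "vo2_L_per_min",
                           col_rq = "rq", vo2_unit = c("L_per_min", "mL_per_min"),
                           delim = ",") {
  vo2_unit <- match.arg(vo2_unit)
  structure(list(col_time = col_time, col_vo2 = col_vo2, col_rq = col_rq,
                 vo2_unit = vo2_unit, delim = delim),
            class = "thermoex_dialect")
}

#' Column-mapping dialect for perspiration-meter exports
#'
#' @param col_time,col_lsr,col_site Column names in the export. Local sweat
#'   rate is expected in mg per cm^2 per minute; site is `"chest"` or `"back"`.
#' @param delim Field delimiter.
#' @return A dialect object (list) accepted by [read_sweat_trace()].
#' @export
sweat_dialect <- function(col_time = "t_s", col_lsr = "lsr_mg_cm2_min",
                          col_site = "site", delim = ",") {
  structure(list(col_time = col_time, col_lsr = col_lsr, col_site = col_site,
                 delim = delim),
            class = "thermoex_dialect")
}

read_delim_checked <- function(path, dialect, required) {
  if (!file.exists(path)) {
    stop("trace file not found: ", path, call. = FALSE)
  }
  df <- readr::read_delim(path, delim = dialect$delim, show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(unlist(dialect[required]), names(df))
  if (length(missing) > 0) {
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

check_monotone <- function(t, what) {
  if (anyNA(t)) stop("validation error: missing timestamps in ", what, call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("validation error: timestamps not strictly increasing in ", what,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a breath-by-breath calorimeter trace
#'
#' Reads one subject's VO2/RQ export, validates timestamp monotonicity and
#' value ranges, and converts VO2 to litres per minute if the dialect declares
#' millilitres.
#'
#' @param path Path to the delimited export.
#' @param dialect A [breath_dialect()].
#' @return A tibble with columns `t` (s from exercise start), `vo2`
#'   (L·min^-1) and `rq`, sorted by `t`.
#' @export
read_breath_trace <- function(path, dialect = breath_dialect()) {
  df <- read_delim_checked(path, dialect, c("col_time", "col_vo2", "col_rq"))
  out <- tibble::tibble(t = as.numeric(df[[dialect$col_time]]),
                        vo2 = as.numeric(df[[dialect$col_vo2]]),
                        rq = as.numeric(df[[dialect$col_rq]]))
  check_monotone(out$t, basename(path))
  if (dialect$vo2_unit == "mL_per_min") out$vo2 <- out$vo2 / 1000
  if (any(out$vo2 < 0, na.rm = TRUE)) {
    stop("validation error: negative VO2 in ", basename(path), call. = FALSE)
  }
  if (any(out$rq <= 0, na.rm = TRUE)) {
    stop("validation error: nonpositive RQ in ", basename(path), call. = FALSE)
  }
  out
}

#' Read a perspiration-meter trace
#'
#' Reads one subject's local sweat rate export (both capsule sites in one
#' file). Timestamps must be strictly increasing within each site.
#'
#' @param path Path to the delimited export.
#' @param dialect A [sweat_dialect()].
#' @return A tibble with columns `t` (s), `lsr` (mg·cm^-2·min^-1) and `site`.
#' @export
read_sweat_trace <- function(path, dialect = sweat_dialect()) {
  df <- read_delim_checked(path, dialect, c("col_time", "col_lsr", "col_site"))
  out <- tibble::tibble(t = as.numeric(df[[dialect$col_time]]),
                        lsr = as.numeric(df[[dialect$col_lsr]]),
                        site = as.character(df[[dialect$col_site]]))
  bad_site <- setdiff(unique(out$site), c("chest", "back"))
  if (length(bad_site) > 0) {
    stop("validation error: unknown site(s) ", paste(bad_site, collapse = ", "),
         " in ", basename(path), call. = FALSE)
  }
  for (s in unique(out$site)) {
    check_monotone(out$t[out$site == s], paste0(basename(path), " [", s, "]"))
  }
  if (any(out$lsr < 0, na.rm = TRUE)) {
    stop("validation error: negative LSR in ", basename(path), call. = FALSE)
  }
  out
}

#' Aggregate 20-s samples to per-minute means
#'
#' Exercise minute m (1-based) collects samples with `t` in the half-open
#' interval `((m-1)*60, m*60]`; the pre-exercise phase collects the final 60 s
#' before exercise start (`t` in `(-60, 0]`) into a single minute-0 resting
#' record. A trailing partial minute is retained only if it holds at least
#' `min_partial` of the 3 samples expected at the nominal 20-s cadence;
#' exhaustion usually terminates exercise mid-minute and discarding all partial
#' minutes would bias late-exercise means.
#'
#' @param samples A data frame with a `t` column (seconds from exercise start)
#'   and one or more value columns.
#' @param cols Character vector of value columns to average.
#' @param phase `"exercise"` or `"pre"`.
#' @param min_partial Minimum samples for a trailing partial minute to be kept.
#' @return A tibble with `minute`, the per-minute mean of each value column,
#'   and `n_samples`.
#' @export
aggregate_per_minute <- function(samples, cols, phase = c("exercise", "pre"),
                                 min_partial = 2) {
  phase <- match.arg(phase)
  stopifnot(is.data.frame(samples), "t" %in% names(samples),
            all(cols %in% names(samples)))
  if (phase == "pre") {
    sub <- samples[samples$t > -60 & samples$t <= 0, , drop = FALSE]
    if (nrow(sub) == 0) stop("no pre-exercise samples in the final 60 s", call. = FALSE)
    out <- tibble::tibble(minute = 0L)
    for (cl in cols) out[[cl]] <- mean(sub[[cl]])
    out$n_samples <- nrow(sub)
    return(out)
  }
  sub <- samples[samples$t > 0, , drop = FALSE]
  if (nrow(sub) == 0) stop("no exercise samples", call. = FALSE)
  minute <- as.integer(ceiling(sub$t / 60))
  last <- max(minute)
  counts <- tabulate(minute, nbins = last)
  if (any(counts[-last] == 0)) {
    stop("gap error: exercise minute(s) ",
         paste(which(counts == 0 & seq_along(counts) < last), collapse = ", "),
         " contain no samples", call. = FALSE)
  }
  keep <- seq_len(last)
  if (counts[last] < min_partial && last > 1) keep <- keep[-last]
  out <- tibble::tibble(minute = keep)
  for (cl in cols) {
    out[[cl]] <- vapply(keep, function(m) mean(sub[[cl]][minute == m]), numeric(1))
  }
  out$n_samples <- counts[keep]
  out
}

#' Maximal oxygen uptake
#'
#' Peak per-minute oxygen uptake scaled to body mass, the usual index of
#' cardiorespiratory fitness from a graded test to exhaustion.
#'
#' @param exercise_minutes A per-minute tibble with a `vo2` column (L·min^-1).
#' @param mass_kg Body mass in kg.
#' @return VO2max in mL·kg^-1·min^-1.
#' @export
max_oxygen_uptake <- function(exercise_minutes, mass_kg) {
  stopifnot(is.data.frame(exercise_minutes), "vo2" %in% names(exercise_minutes),
            nrow(exercise_minutes) > 0)
  if (!is.finite(mass_kg) || mass_kg <= 0) {
    stop("max_oxygen_uptake(): mass must be > 0", call. = FALSE)
  }
  max(exercise_minutes$vo2) * 1000 / mass_kg
}
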