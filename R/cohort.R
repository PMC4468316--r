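#' Classify a subject from constitutional-type probability scores
#'
#' Assigns the Sasang type (TE, SE or SY) with the highest probability score,
#' excluding subjects whose classification is ambiguous: a highest score below
#' 0.40, or a gap between the highest and middle score below 0.05. The middle
#' score is the median of the three; a tied maximum therefore yields a zero
#' margin and an `ambiguous_margin` exclusion. Scores are used as given — they
#' are tool outputs and need not sum to one.
#'
#' @param te,se,sy Numeric probability scores in `[0, 1]`, vectorised.
#' @param min_top Minimum acceptable highest score (default 0.40).
#' @param min_margin Minimum gap between highest and middle score (default 0.05).
#' @return Character vector: `"TE"`, `"SE"`, `"SY"`, `"low_top_score"` or
#'   `"ambiguous_margin"`.
#' @export
classify_sasang <- function(te, se, sy, min_top = 0.40, min_margin = 0.05) {
  n <- length(te)
  stopifnot(length(se) == n, length(sy) == n)
  s <- cbind(te, se, sy)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("classify_sasang(): scores must be finite and in [0, 1]", call. = FALSE)
  }
  labs <- c("TE", "SE", "SY")
  vapply(seq_len(n), function(i) {
    v <- s[i, ]
    top <- max(v)
    if (top < min_top) return("low_top_score")
    if (top - stats::median(v) < min_margin) return("ambiguous_margin")
    labs[which.max(v)]
  }, character(1))
}

#' Flag an unusual early-exercise sweating pattern
#'
#' The study's quality filter removes subjects whose sweating was not a steady
#' rise but showed an abrupt increase and decrease during the early phase of
#' exercise. Operationally: within the first half of exercise, a
#' minute-to-minute rise exceeding `theta_rise` followed within two minutes by
#' a fall exceeding `theta_fall` flags the trace.
#'
#' @param lsr Per-minute local sweat rate values (mg·cm^-2·min^-1), minute 1
#'   first.
#' @param theta_rise,theta_fall Rise/fall thresholds in the same units
#'   (default 0.3).
#' @return A list with `flagged`, `evaluable`, and the offending `minutes`
#'   (index of the minute where the abrupt rise begins).
#' @export
flag_unusual_sweat <- function(lsr, theta_rise = 0.3, theta_fall = 0.3) {
  n <- length(lsr)
  if (n < 4) {
    warning("LSR series too short to evaluate sweat-pattern QC; not flagged")
    return(list(flagged = FALSE, evaluable = FALSE, minutes = integer(0)))
  }
  half <- ceiling(n / 2)
  d <- diff(lsr)
  offending <- integer(0)
  for (m in seq_len(max(half - 1, 1))) {
    if (m + 1 > half) break
    if (d[m] > theta_rise) {
      peak <- lsr[m + 1]
      ahead <- lsr[seq(m + 2, min(m + 3, n))]
      if (length(ahead) > 0 && max(peak - ahead) > theta_fall) {
        offending <- c(offending, m)
      }
    }
  }
  list(flagged = length(offending) > 0, evaluable = TRUE, minutes = offending)
}

#' Assemble the analyzable cohort
#'
#' Applies the exclusion rules in the study's order: constitutional-score rules
#' first, then the unusual-sweat-pattern quality filter, then a missing-VO2
#' check. Each excluded subject carries exactly one primary reason (the first
#' failing rule).
#'
#' @param participants Participant table with columns `id`, `sex`, `score_te`,
#'   `score_se`, `score_sy` (plus anthropometrics passed through).
#' @param breath_traces Named list (by id) of breath traces as returned by
#'   [read_breath_trace()]; subjects absent from the list, or with empty
#'   traces, fail the missing-VO2 check. Score-excluded subjects need no trace.
#' @param sweat_minutes Named list (by id) of per-minute LSR tibbles with
#'   columns `site`, `minute`, `lsr` (see [aggregate_per_minute()]); used for
#'   the sweat-pattern QC. A subject is flagged if either capsule site is.
#' @param theta_rise,theta_fall Sweat-QC thresholds, see [flag_unusual_sweat()].
#' @return A list with `included` (participant rows plus a `group` column) and
#'   `exclusions` (tibble of `id`, `reason`).
#' @export
assemble_cohort <- function(participants, breath_traces = list(),
                            sweat_minutes = list(),
                            theta_rise = 0.3, theta_fall = 0.3) {
  req <- c("id", "sex", "score_te", "score_se", "score_sy")
  stopifnot(all(req %in% names(participants)))
  if (anyDuplicated(participants$id)) {
    stop("duplicate participant ids", call. = FALSE)
  }
  orphans <- setdiff(c(names(breath_traces), names(sweat_minutes)),
                     as.character(participants$id))
  if (length(orphans) > 0) {
    stop("orphan-record error: trace(s) without participant row: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(participants) == 0) {
    return(list(included = cbind(participants, group = character(0)),
                exclusions = tibble::tibble(id = character(0), reason = character(0))))
  }
  cls <- classify_sasang(participants$score_te, participants$score_se,
                         participants$score_sy)
  reason <- ifelse(cls %in% c("TE", "SE", "SY"), NA_character_, cls)
  for (i in which(is.na(reason))) {
    id <- as.character(participants$id[i])
    sm <- sweat_minutes[[id]]
    flagged <- FALSE
    if (!is.null(sm) && nrow(sm) > 0) {
      for (s in unique(sm$site)) {
        v <- sm$lsr[sm$site == s][order(sm$minute[sm$site == s])]
        fl <- suppressWarnings(flag_unusual_sweat(v, theta_rise, theta_fall))
        if (fl$flagged) flagged <- TRUE
      }
    }
    if (flagged) {
      reason[i] <- "unusual_sweat"
    } else {
      bt <- breath_traces[[id]]
      if (is.null(bt) || nrow(bt) == 0) reason[i] <- "missing_vo2"
    }
  }
  included <- participants[is.na(reason), , drop = FALSE]
  included$group <- cls[is.na(reason)]
  list(included = tibble::as_tibble(included),
       exclusions = tibble::tibble(id = participants$id[!is.na(reason)],
                                   reason = reason[!is.na(reason)]))
}

#' Stratified cohort counts
#'
#' @param included The `included` table from [assemble_cohort()].
#' @return A tibble of counts by `sex` and `group`.
#' @export
cohort_counts <- function(included) {
  dplyr::count(included, .data$sex, .data$group, name = "n")
}
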