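#' Truncated-normal sampler
#'
#' Inverse-CDF sampling of a normal restricted to `[lo, hi]`. The generator
#' truncates at mean +/- 4 SD and at physiologic floors so extreme tails never
#' produce impossible anthropometrics.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of draws.
#' @export
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop("rtruncnorm(): sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    if (any(mean < lo) || any(mean > hi)) {
      stop("spec error: degenerate mean outside bounds", call. = FALSE)
    }
    return(rep(mean, n))
  }
  if (any(lo >= hi)) stop("spec error: impossible truncation bounds", call. = FALSE)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Default cohort cells
#'
#' Per sex-by-type cell sizes and anthropometric means/SDs of the analyzed
#' cohort (ages in years, masses in kg, height in cm, exercise time in
#' minutes). Exercise-time calibration: TE males 11.1 (1.1), SY males 12.4
#' (1.4), TE females 9.8 (1.3), SY females 10.4 (1.1); SE times are not
#' printed in the source tables and are set between the others, consistent
#' with SE males exercising longer than TE males and SE females matching TE
#' females.
#'
#' @return A tibble with one row per sex-by-type cell.
#' @export
default_cells <- function() {
  tibble::tribble(
    ~sex, ~group, ~n, ~age_mean, ~age_sd, ~weight_mean, ~weight_sd,
    ~height_mean, ~height_sd, ~bfm_mean, ~bfm_sd, ~water_mean, ~water_sd,
    ~extime_mean, ~extime_sd, ~peak_vo2_ml_kg_mean, ~peak_vo2_ml_kg_sd,
    "male",   "TE", 62L, 29.8, 6.1, 82.6, 9.4, 174.9, 5.5, 21.1, 6.5, 45.1, 4.3, 11.1, 1.1, 38, 4,
    "male",   "SE", 59L, 30.1, 6.3, 62.8, 6.4, 172.3, 5.3, 10.6, 3.4, 38.4, 3.5, 12.0, 1.3, 52, 4,
    "male",   "SY", 57L, 29.8, 6.2, 70.8, 6.4, 173.5, 5.5, 13.3, 4.0, 42.2, 3.3, 12.4, 1.4, 48, 4,
    "female", "TE", 46L, 31.9, 6.7, 64.0, 7.2, 159.9, 5.1, 21.5, 5.2, 31.1, 3.0,  9.8, 1.3, 34, 4,
    "female", "SE", 40L, 30.6, 7.1, 50.9, 4.3, 161.3, 5.2, 13.1, 3.1, 27.8, 2.7, 10.0, 1.2, 46, 4,
    "female", "SY", 40L, 28.1, 5.2, 52.5, 4.0, 159.0, 5.7, 14.2, 2.8, 28.1, 2.7, 10.4, 1.1, 44, 4
  )
}

#' Forward-model parameters for synthetic instrument traces
#'
#' VO2 follows a stage-wise mono-exponential rise from a resting level toward
#' a subject peak; RQ drifts from ~0.80 at start toward ~1.05 at exhaustion;
#' local sweat rate is flat near zero until a per-site onset delay, then rises
#' linearly with a group-specific slope multiplier (TE > SY > SE, the ordering
#' the analysis should recover). All observed at a 20-s cadence with Gaussian
#' noise.
#'
#' @param resting_vo2_ml_kg Resting VO2, mL·kg^-1·min^-1.
#' @param tau_s Mono-exponential time constant, s.
#' @param rq_start,rq_end RQ at exercise start and at exhaustion.
#' @param vo2_noise_sd,rq_noise_sd,lsr_noise_sd Observation noise SDs.
#' @param onset_chest_min,onset_back_min Sweat onset delays, min.
#' @param lsr_slope Post-onset rise, mg·cm^-2·min^-1 per minute, before the
#'   group multiplier.
#' @param slope_multiplier Named group multipliers.
#' @param cadence_s Sampling cadence, s.
#' @return Parameter list.
#' @export
trace_spec <- function(resting_vo2_ml_kg = 3.5, tau_s = 30,
                       rq_start = 0.80, rq_end = 1.05,
                       vo2_noise_sd = 0.05, rq_noise_sd = 0.02,
                       lsr_noise_sd = 0.02,
                       onset_chest_min = 4, onset_back_min = 3.5,
                       lsr_slope = 0.06,
                       slope_multiplier = c(TE = 1.4, SY = 1.0, SE = 0.7),
                       cadence_s = 20) {
  as.list(environment())
}

#' Full synthetic-study specification
#'
#' @param seed Mandatory RNG seed; every downstream draw is reproducible from
#'   it.
#' @param cells Sex-by-type cell table, see [default_cells()].
#' @param n_fail_scores Number of extra subjects constructed to fail the
#'   constitutional-score exclusion rules (default 237, the study's
#'   bookkeeping).
#' @param n_fail_downstream Number of extra subjects failing the downstream
#'   checks (default 9: unusual sweat pattern or missing VO2).
#' @param trace Trace forward-model parameters, see [trace_spec()].
#' @return Specification list for [generate_cohort()] / [generate_study()].
#' @export
cohort_spec <- function(seed, cells = default_cells(),
                        n_fail_scores = 237L, n_fail_downstream = 9L,
                        trace = trace_spec()) {
  if (missing(seed) || !is.finite(seed)) stop("cohort_spec(): seed is mandatory",
                                              call. = FALSE)
  stopifnot(n_fail_scores >= 0, n_fail_downstream >= 0,
            all(cells$n >= 0))
  list(seed = as.integer(seed), cells = cells,
       n_fail_scores = as.integer(n_fail_scores),
       n_fail_downstream = as.integer(n_fail_downstream),
       trace = trace)
}

sample_cell_anthro <- function(cell, n) {
  wt <- rtruncnorm(n, cell$weight_mean, cell$weight_sd,
                   max(30, cell$weight_mean - 4 * cell$weight_sd),
                   cell$weight_mean + 4 * cell$weight_sd)
  ht <- rtruncnorm(n, cell$height_mean, cell$height_sd,
                   max(120, cell$height_mean - 4 * cell$height_sd),
                   cell$height_mean + 4 * cell$height_sd)
  bfm <- rtruncnorm(n, cell$bfm_mean, cell$bfm_sd,
                    max(2, cell$bfm_mean - 4 * cell$bfm_sd),
                    pmin(cell$bfm_mean + 4 * cell$bfm_sd, 0.6 * wt))
  water <- rtruncnorm(n, cell$water_mean, cell$water_sd,
                      max(15, cell$water_mean - 4 * cell$water_sd),
                      cell$water_mean + 4 * cell$water_sd)
  age <- round(rtruncnorm(n, cell$age_mean, cell$age_sd, 20, 49), 1)
  peak <- rtruncnorm(n, cell$peak_vo2_ml_kg_mean, cell$peak_vo2_ml_kg_sd,
                     max(15, cell$peak_vo2_ml_kg_mean - 4 * cell$peak_vo2_ml_kg_sd),
                     cell$peak_vo2_ml_kg_mean + 4 * cell$peak_vo2_ml_kg_sd)
  dur <- rtruncnorm(n, cell$extime_mean, cell$extime_sd,
                    max(4, cell$extime_mean - 4 * cell$extime_sd),
                    cell$extime_mean + 4 * cell$extime_sd)
  tibble::tibble(
    sex = cell$sex, age = age, weight_kg = round(wt, 1),
    height_cm = round(ht, 1), bfm_kg = round(bfm, 1),
    ffm_kg = round(wt, 1) - round(bfm, 1), body_water_kg = round(water, 1),
    peak_vo2_ml_kg = peak,
    duration_min = round(dur * 3) / 3 # exhaustion aligned to the 20-s cadence
  )
}

passing_scores <- function(n, group) {
  top <- stats::runif(n, 0.45, 0.85)
  second <- pmax(top - stats::runif(n, 0.07, 0.35), 0.01)
  third <- pmax(second - stats::runif(n, 0.02, 0.25), 0.0)
  m <- matrix(0, n, 3, dimnames = list(NULL, c("TE", "SE", "SY")))
  others <- lapply(group, function(gr) setdiff(c("TE", "SE", "SY"), gr))
  for (i in seq_len(n)) {
    m[i, group[i]] <- top[i]
    m[i, others[[i]][1]] <- second[i]
    m[i, others[[i]][2]] <- third[i]
  }
  round(m, 2)
}

failing_scores <- function(n) {
  # alternate low-top-score and ambiguous-margin failures
  m <- matrix(0, n, 3, dimnames = list(NULL, c("TE", "SE", "SY")))
  for (i in seq_len(n)) {
    perm <- sample(1:3)
    if (i %% 2 == 1) {
      top <- stats::runif(1, 0.20, 0.389)
      m[i, perm] <- round(c(top, stats::runif(1, 0.1, top),
                            stats::runif(1, 0, 0.2)), 2)
      m[i, perm[1]] <- min(m[i, perm[1]], 0.39)
    } else {
      top <- stats::runif(1, 0.42, 0.70)
      second <- top - stats::runif(1, 0.0, 0.04)
      m[i, perm] <- round(c(top, second, stats::runif(1, 0, 0.2)), 2)
      # rounding to 2 dp keeps the margin below 0.05
      if (m[i, perm[1]] - m[i, perm[2]] >= 0.05) m[i, perm[2]] <- m[i, perm[1]]
    }
  }
  m
}

#' Generate a synthetic participant cohort
#'
#' Samples anthropometrics from truncated normals per sex-by-type cell,
#' assigns constitutional score vectors so that exactly `n_fail_scores`
#' subjects fail the score rules and `n_fail_downstream` fail the downstream
#' checks (unusual sweat pattern or missing VO2), and returns ground truth
#' next to the observable columns. Fat-free mass is derived as weight minus
#' fat mass so the composition identity holds exactly.
#'
#' @param spec A [cohort_spec()]. The spec's seed is set at entry.
#' @return A list with `participants` (observable table) and `truth`
#'   (per-subject generating values incl. `true_group`, `fail_mode`,
#'   `duration_min`, `peak_vo2_ml_kg`).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  cells <- spec$cells
  groups3 <- c("TE", "SE", "SY")
  blocks <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    if (cell$n == 0) next
    b <- sample_cell_anthro(cell, cell$n)
    b$true_group <- cell$group
    b$fail_mode <- "none"
    blocks[[length(blocks) + 1]] <- b
  }
  # extra subjects that the exclusion rules must remove, drawn by cycling cells
  extra <- function(n, fail_mode_fun) {
    if (n == 0) return(NULL)
    idx <- rep(seq_len(nrow(cells)), length.out = n)
    bl <- lapply(seq_len(n), function(j) {
      b <- sample_cell_anthro(cells[idx[j], ], 1)
      b$true_group <- cells$group[idx[j]]
      b$fail_mode <- fail_mode_fun(j)
      b
    })
    dplyr::bind_rows(bl)
  }
  sc_fail <- extra(spec$n_fail_scores, function(j) "scores")
  dn_fail <- extra(spec$n_fail_downstream,
                   function(j) if (j %% 2 == 1) "unusual_sweat" else "missing_vo2")
  truth <- dplyr::bind_rows(c(blocks, list(sc_fail, dn_fail)))
  n_all <- nrow(truth)
  truth$id <- sprintf("S%04d", seq_len(n_all))
  sc <- matrix(NA_real_, n_all, 3, dimnames = list(NULL, groups3))
  pass <- truth$fail_mode != "scores"
  if (any(pass)) sc[pass, ] <- passing_scores(sum(pass), truth$true_group[pass])
  if (any(!pass)) sc[!pass, ] <- failing_scores(sum(!pass))
  participants <- tibble::tibble(
    id = truth$id, sex = truth$sex, age = truth$age,
    weight_kg = truth$weight_kg, height_cm = truth$height_cm,
    ffm_kg = truth$ffm_kg, bfm_kg = truth$bfm_kg,
    body_water_kg = truth$body_water_kg,
    score_te = sc[, "TE"], score_se = sc[, "SE"], score_sy = sc[, "SY"]
  )
  truth <- tibble::as_tibble(truth[, c("id", "sex", "true_group", "fail_mode",
                                       "duration_min", "peak_vo2_ml_kg",
                                       "weight_kg", "body_water_kg")])
  list(participants = participants, truth = truth)
}

#' Generate a synthetic breath-by-breath trace for one subject
#'
#' VO2 rises mono-exponentially within each 3-minute stage toward a stagewise
#' asymptote that climbs linearly from the resting level to the subject's peak
#' at the final stage; RQ drifts linearly from `rq_start` to `rq_end` over the
#' bout. Includes a 60-s pre-exercise resting segment (t = -40, -20, 0 s).
#'
#' @param subject One-row list/tibble with `weight_kg`, `peak_vo2_ml_kg`,
#'   `duration_min`.
#' @param tspec A [trace_spec()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Tibble of samples `t`, `vo2` (L·min^-1), `rq`.
#' @export
generate_breath_trace <- function(subject, tspec = trace_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur_s <- subject$duration_min * 60
  stopifnot(dur_s > 0)
  rest <- tspec$resting_vo2_ml_kg * subject$weight_kg / 1000
  peak <- subject$peak_vo2_ml_kg * subject$weight_kg / 1000
  n_stages <- ceiling(subject$duration_min / 3)
  asym <- rest + (peak - rest) * seq_len(n_stages) / n_stages
  # deterministic level at the start of each stage
  start_level <- numeric(n_stages)
  start_level[1] <- rest
  if (n_stages > 1) {
    for (s in 2:n_stages) {
      dt <- 180
      start_level[s] <- asym[s - 1] +
        (start_level[s - 1] - asym[s - 1]) * exp(-dt / tspec$tau_s)
    }
  }
  t_ex <- seq(tspec$cadence_s, dur_s, by = tspec$cadence_s)
  s_idx <- pmin(ceiling(t_ex / 180), n_stages)
  t_in_stage <- t_ex - (s_idx - 1) * 180
  vo2_det <- asym[s_idx] + (start_level[s_idx] - asym[s_idx]) *
    exp(-t_in_stage / tspec$tau_s)
  rq_det <- tspec$rq_start + (tspec$rq_end - tspec$rq_start) * t_ex / dur_s
  t_pre <- c(-40, -20, 0)
  vo2 <- c(rest + stats::rnorm(3, 0, tspec$vo2_noise_sd / 2),
           vo2_det + stats::rnorm(length(t_ex), 0, tspec$vo2_noise_sd))
  rq <- c(rep(tspec$rq_start, 3) + stats::rnorm(3, 0, tspec$rq_noise_sd),
          rq_det + stats::rnorm(length(t_ex), 0, tspec$rq_noise_sd))
  tibble::tibble(t = c(t_pre, t_ex), vo2 = pmax(vo2, 0.01), rq = pmax(rq, 0.5))
}

#' Generate synthetic perspiration-meter traces for one subject
#'
#' Piecewise-linear forward model per capsule site: baseline near zero before
#' the onset delay, then a linear rise whose slope carries the subject's
#' group multiplier. Subjects marked `unusual_sweat` get an abrupt
#' spike-and-drop planted in exercise minute 3 on the chest, the pattern the
#' quality filter must catch.
#'
#' @inheritParams generate_breath_trace
#' @param subject One-row list/tibble with `duration_min`, `true_group`,
#'   `fail_mode`.
#' @return Tibble of samples `t`, `lsr`, `site` (chest and back interleaved).
#' @export
generate_sweat_trace <- function(subject, tspec = trace_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur_s <- subject$duration_min * 60
  t_ex <- seq(tspec$cadence_s, dur_s, by = tspec$cadence_s)
  mult <- tspec$slope_multiplier[[subject$true_group]]
  one_site <- function(site, onset_min) {
    det <- tspec$lsr_slope * mult * pmax(t_ex / 60 - onset_min, 0)
    lsr <- det + stats::rnorm(length(t_ex), 0, tspec$lsr_noise_sd)
    if (identical(subject$fail_mode, "unusual_sweat") && site == "chest") {
      lsr[t_ex > 120 & t_ex <= 180] <- lsr[t_ex > 120 & t_ex <= 180] + 0.9
    }
    tibble::tibble(t = t_ex, lsr = pmax(lsr, 0), site = site)
  }
  dplyr::bind_rows(one_site("chest", tspec$onset_chest_min),
                   one_site("back", tspec$onset_back_min))
}

#' Generate a full synthetic study in memory
#'
#' Cohort plus traces: breath and sweat traces are generated for every subject
#' that passes the score rules (score-excluded subjects were never measured),
#' except that `missing_vo2` subjects get no breath trace.
#'
#' @param spec A [cohort_spec()].
#' @return List with `participants`, `truth`, `breath` (named list of breath
#'   traces) and `sweat` (named list of sweat traces).
#' @export
generate_study_data <- function(spec) {
  ch <- generate_cohort(spec)
  breath <- list()
  sweat <- list()
  for (i in seq_len(nrow(ch$truth))) {
    tr <- ch$truth[i, ]
    if (tr$fail_mode == "scores") next
    sweat[[tr$id]] <- generate_sweat_trace(tr, spec$trace)
    if (tr$fail_mode != "missing_vo2") {
      breath[[tr$id]] <- generate_breath_trace(tr, spec$trace)
    }
  }
  list(participants = ch$participants, truth = ch$truth,
       breath = breath, sweat = sweat)
}

#' Write a synthetic study bundle to disk
#'
#' Produces the same CSV dialects the ingest functions read: a participant
#' table, one breath trace and one sweat trace per measured subject, the
#' ground-truth table (synthetic studies only), the serialized spec and a
#' manifest recording the seed and spec hash. Two runs with the same spec are
#' byte-identical.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory study (see [generate_study_data()]) plus
#'   `dir`.
#' @export
generate_study <- function(spec, dir) {
  study <- generate_study_data(spec)
  dir.create(file.path(dir, "breath"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sweat"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$participants, file.path(dir, "participants.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth_synthetic.csv"))
  for (id in names(study$breath)) {
    b <- study$breath[[id]]
    names(b) <- c("t_s", "vo2_L_per_min", "rq")
    readr::write_csv(b, file.path(dir, "breath", paste0(id, ".csv")))
  }
  for (id in names(study$sweat)) {
    s <- study$sweat[[id]]
    names(s) <- c("t_s", "lsr_mg_cm2_min", "site")
    readr::write_csv(s, file.path(dir, "sweat", paste0(id, ".csv")))
  }
  spec_json <- file.path(dir, "spec.json")
  ser <- spec
  ser$cells <- as.data.frame(ser$cells)
  jsonlite::write_json(ser, spec_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(seed = spec$seed,
                   n_participants = nrow(study$participants),
                   n_breath_traces = length(study$breath),
                   n_sweat_traces = length(study$sweat),
                   spec_md5 = unname(tools::md5sum(spec_json)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(study, list(dir = dir)))
}
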