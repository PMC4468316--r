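#' Pipeline configuration
#'
#' One object holding every tunable the analysis uses, so a run is fully
#' reproducible from its manifest.
#'
#' @param alpha Significance level for all tests.
#' @param min_n Minimum per-group n for a tested exercise minute.
#' @param theta_rise,theta_fall Sweat-pattern QC thresholds
#'   (mg·cm^-2·min^-1), see [flag_unusual_sweat()].
#' @param eps Denominator mask threshold for sweat normalization.
#' @param protocol Treadmill schedule, see [bruce_protocol()].
#' @param clamp_rq,floor_tinc Energetics conventions, see
#'   [metabolic_energy()] and [temperature_increment()].
#' @param min_partial Minimum samples for a trailing partial minute.
#' @param outcomes Per-minute outcomes entered into the group comparisons.
#' @return Configuration list.
#' @export
pipeline_config <- function(alpha = 0.05, min_n = 2,
                            theta_rise = 0.3, theta_fall = 0.3,
                            eps = 1e-6, protocol = bruce_protocol(),
                            clamp_rq = TRUE, floor_tinc = TRUE,
                            min_partial = 2,
                            outcomes = c("w_e", "m_ee", "efficiency_pct",
                                         "t_inc_cum",
                                         "lsr_chest", "lsr_back",
                                         "wsr_chest", "wsr_back",
                                         "wsr_chest_per_we", "wsr_back_per_we",
                                         "wsr_chest_per_hprod", "wsr_back_per_hprod",
                                         "wsr_chest_per_tinc", "wsr_back_per_tinc")) {
  as.list(environment())
}

aggregate_sweat_minutes <- function(trace, min_partial = 2) {
  parts <- lapply(unique(trace$site), function(s) {
    m <- aggregate_per_minute(trace[trace$site == s, ], "lsr",
                              phase = "exercise", min_partial = min_partial)
    m$site <- s
    m
  })
  dplyr::bind_rows(parts)
}

subject_minutes <- function(id, sex, group, breath, sweat, bsa,
                            weight_kg, body_water_kg, config) {
  pre <- aggregate_per_minute(breath, c("vo2", "rq"), phase = "pre")
  ex <- aggregate_per_minute(breath, c("vo2", "rq"), phase = "exercise",
                             min_partial = config$min_partial)
  bm <- dplyr::bind_rows(pre, ex)
  en <- build_energetics_series(bm, protocol = config$protocol,
                                weight_kg = weight_kg,
                                body_water_kg = body_water_kg,
                                clamp_rq = config$clamp_rq,
                                floor_tinc = config$floor_tinc)
  tab <- en$minutes
  tab$vo2 <- ex$vo2[match(tab$minute, ex$minute)]
  sm <- aggregate_sweat_minutes(sweat, config$min_partial)
  for (s in c("chest", "back")) {
    v <- sm[sm$site == s, c("minute", "lsr")]
    names(v) <- c("minute", "value")
    common <- intersect(v$minute, tab$minute)
    lsr <- v$value[match(tab$minute, v$minute)]
    tab[[paste0("lsr_", s)]] <- lsr
    wsr <- ifelse(is.na(lsr), NA_real_, whole_body_rate(pmax(lsr, 0), bsa))
    tab[[paste0("wsr_", s)]] <- wsr
    sub <- tab[tab$minute %in% common, ]
    for (dn in c("we", "hprod", "tinc")) {
      den_col <- switch(dn, we = "w_e", hprod = "h_prod", tinc = "t_inc_cum")
      nz <- normalize_sweat(
        tibble::tibble(minute = sub$minute, value = sub[[paste0("wsr_", s)]]),
        tibble::tibble(minute = sub$minute, value = sub[[den_col]]),
        eps = config$eps, label = den_col)
      tab[[paste0("wsr_", s, "_per_", dn)]] <-
        nz$value[match(tab$minute, nz$minute)]
      nzl <- normalize_sweat(
        tibble::tibble(minute = sub$minute, value = sub[[paste0("lsr_", s)]]),
        tibble::tibble(minute = sub$minute, value = sub[[den_col]]),
        eps = config$eps, label = den_col)
      tab[[paste0("lsr_", s, "_per_", dn)]] <-
        nzl$value[match(tab$minute, nzl$minute)]
    }
  }
  # per-minute increments of the sweat-derived series (first minute undefined)
  inc_cols <- grep("^(lsr|wsr)_", names(tab), value = TRUE)
  if (nrow(tab) >= 2) {
    for (cl in inc_cols) {
      tab[[paste0("d_", cl)]] <- c(NA_real_, diff(tab[[cl]]))
    }
  }
  tab <- tibble::add_column(tab, id = id, sex = sex, group = group,
                            .before = 1)
  list(minutes = tab, totals = en$totals, m_ee_rest = en$m_ee_rest,
       vo2max = max_oxygen_uptake(ex, weight_kg),
       duration_min = max(breath$t) / 60)
}

#' Run the full analysis on an in-memory study
#'
#' Cohort assembly (score classification, sweat-pattern QC, missing-VO2
#' check), per-subject energetics and sweat series, scalar totals with
#' ANOVA/Tukey comparisons, and per-minute Kruskal-Wallis/Nemenyi comparisons
#' stratified by sex.
#'
#' @param participants Participant table (see [assemble_cohort()] for the
#'   required columns).
#' @param breath Named list (by id) of breath traces.
#' @param sweat Named list (by id) of sweat traces.
#' @param config A [pipeline_config()].
#' @return A report list: `included`, `exclusions`, `counts`,
#'   `subject_totals`, `totals_summary`, `minutes` (long per-subject-minute
#'   table) and `comparisons` (per-minute test results per outcome and sex).
#' @export
analyze_study <- function(participants, breath, sweat,
                          config = pipeline_config()) {
  sweat_minutes <- lapply(sweat, aggregate_sweat_minutes,
                          min_partial = config$min_partial)
  coh <- assemble_cohort(participants, breath, sweat_minutes,
                         theta_rise = config$theta_rise,
                         theta_fall = config$theta_fall)
  included <- coh$included
  if (nrow(included) == 0) {
    warning("empty cohort after exclusions; report tables are empty")
    return(list(included = included, exclusions = coh$exclusions,
                counts = tibble::tibble(), subject_totals = tibble::tibble(),
                totals_summary = tibble::tibble(), minutes = tibble::tibble(),
                comparisons = tibble::tibble(), config = config))
  }
  included <- add_anthropometry(included)
  per_subject <- lapply(seq_len(nrow(included)), function(i) {
    p <- included[i, ]
    id <- as.character(p$id)
    subject_minutes(id, p$sex, p$group, breath[[id]], sweat[[id]],
                    bsa = p$bsa_m2, weight_kg = p$weight_kg,
                    body_water_kg = p$body_water_kg, config = config)
  })
  minutes <- dplyr::bind_rows(lapply(per_subject, `[[`, "minutes"))
  subject_totals <- dplyr::bind_rows(lapply(seq_along(per_subject), function(i) {
    t <- per_subject[[i]]$totals
    tibble::tibble(id = as.character(included$id[i]), sex = included$sex[i],
                   group = included$group[i],
                   exercise_time_min = per_subject[[i]]$duration_min,
                   total_w_e = t$total_w_e, total_m_ee = t$total_m_ee,
                   total_h_prod = t$total_h_prod,
                   efficiency_pct = t$mean_efficiency,
                   vo2max_ml_kg_min = per_subject[[i]]$vo2max,
                   m_ee_rest = per_subject[[i]]$m_ee_rest)
  }))
  totals_summary <- summarize_totals(subject_totals, alpha = config$alpha)
  comparisons <- compare_timecourses(minutes, config)
  list(included = included, exclusions = coh$exclusions,
       counts = cohort_counts(included), subject_totals = subject_totals,
       totals_summary = totals_summary, minutes = minutes,
       comparisons = comparisons, config = config)
}

#' Scalar-summary table with ANOVA and Tukey comparisons
#'
#' Mean (SD) per sex-by-type cell for exercise time, total external workload,
#' total metabolic energy expenditure and metabolic efficiency, with the
#' one-way ANOVA p-value and Tukey HSD pairwise significance letters
#' (`a` TE-SE, `b` TE-SY, `c` SE-SY) appended per sex.
#'
#' @param subject_totals Per-subject totals as produced by [analyze_study()].
#' @param alpha Significance level.
#' @param measures Which total columns to summarize.
#' @return Tibble with one row per sex and measure.
#' @export
summarize_totals <- function(subject_totals, alpha = 0.05,
                             measures = c("exercise_time_min", "total_w_e",
                                          "total_m_ee", "efficiency_pct",
                                          "vo2max_ml_kg_min")) {
  groups <- c("TE", "SE", "SY")
  out <- list()
  for (sx in unique(subject_totals$sex)) {
    sub <- subject_totals[subject_totals$sex == sx, ]
    for (ms in measures) {
      row <- tibble::tibble(sex = sx, measure = ms)
      for (gr in groups) {
        v <- sub[[ms]][sub$group == gr]
        row[[paste0("n_", tolower(gr))]] <- length(v)
        row[[paste0("mean_", tolower(gr))]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0("sd_", tolower(gr))]] <-
          if (length(v) > 1) stats::sd(v) else NA_real_
      }
      enough <- all(table(factor(sub$group, levels = groups)) >= 2)
      if (enough && stats::var(sub[[ms]]) > 0) {
        an <- one_way_anova(sub[[ms]], sub$group)
        row$p_anova <- an$p
        tk <- tukey_hsd(sub[[ms]], sub$group, alpha = alpha)
        sig <- function(a, b) {
          any(tk$significant[tk$pair %in% c(paste(a, b, sep = "-"),
                                            paste(b, a, sep = "-"))])
        }
        row$tukey_letters <- paste(c(if (sig("TE", "SE")) "a",
                                     if (sig("TE", "SY")) "b",
                                     if (sig("SE", "SY")) "c"),
                                   collapse = "")
      } else {
        row$p_anova <- NA_real_
        row$tukey_letters <- ""
      }
      out[[length(out) + 1]] <- row
    }
  }
  dplyr::bind_rows(out)
}

compare_timecourses <- function(minutes, config) {
  out <- list()
  for (sx in unique(minutes$sex)) {
    for (oc in config$outcomes) {
      if (!oc %in% names(minutes)) next
      d <- tibble::tibble(id = minutes$id[minutes$sex == sx],
                          group = minutes$group[minutes$sex == sx],
                          minute = minutes$minute[minutes$sex == sx],
                          value = minutes[[oc]][minutes$sex == sx])
      tc <- timecourse_compare(d, alpha = config$alpha, min_n = config$min_n)
      tc <- tibble::add_column(tc, sex = sx, outcome = oc, .before = 1)
      out[[length(out) + 1]] <- tc
    }
  }
  dplyr::bind_rows(out)
}

#' Run the pipeline on an on-disk study bundle
#'
#' Reads a bundle laid out as written by [generate_study()] (participants.csv
#' plus breath/ and sweat/ trace directories), runs [analyze_study()], and
#' optionally writes the report tables and a run manifest as CSV/JSON.
#'
#' @param input_dir Bundle directory.
#' @param out_dir Optional output directory for report CSVs.
#' @param config A [pipeline_config()].
#' @return The report list from [analyze_study()].
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         config = pipeline_config()) {
  pfile <- file.path(input_dir, "participants.csv")
  if (!file.exists(pfile)) stop("participants.csv not found in ", input_dir,
                                call. = FALSE)
  participants <- readr::read_csv(pfile, show_col_types = FALSE, progress = FALSE)
  read_dir <- function(sub, reader) {
    files <- list.files(file.path(input_dir, sub), pattern = "\\.csv$",
                        full.names = TRUE)
    out <- lapply(files, reader)
    names(out) <- sub("\\.csv$", "", basename(files))
    out
  }
  breath <- read_dir("breath", read_breath_trace)
  sweat <- read_dir("sweat", read_sweat_trace)
  report <- analyze_study(participants, breath, sweat, config)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write report tables to CSV
#'
#' @param report Report list from [analyze_study()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (is.data.frame(x) && nrow(x) > 0) {
      readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
    }
  }
  wr(report$counts, "cohort_counts")
  wr(report$exclusions, "exclusion_ledger")
  wr(report$subject_totals, "subject_totals")
  wr(report$totals_summary, "totals_summary")
  wr(report$minutes, "per_minute_values")
  wr(report$comparisons, "per_minute_comparisons")
  cfg <- report$config
  cfg$protocol <- as.data.frame(cfg$protocol)
  jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
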