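check_groups <- function(x, g, min_n = 2) {
  g <- factor(g)
  if (length(x) != length(g)) stop("x and g lengths differ", call. = FALSE)
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  n <- table(g)
  if (nlevels(g) < 2) stop("insufficient-data error: need >= 2 groups", call. = FALSE)
  if (any(n < min_n)) {
    stop("insufficient-data error: group(s) ",
         paste(names(n)[n < min_n], collapse = ", "), " have n < ", min_n,
         call. = FALSE)
  }
  list(x = x, g = g, n = n)
}

pair_labels <- function(levels) {
  cmb <- utils::combn(levels, 2)
  paste(cmb[1, ], cmb[2, ], sep = "-")
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects F test for scalar summaries (exercise time, total
#' workload, total energy expenditure, efficiency) across constitutional
#' groups within a sex stratum.
#'
#' @param x Numeric observations.
#' @param g Group labels (coerced to factor).
#' @return A list with `statistic` (F), `df`, `p`, `n` per group and a
#'   `degenerate` flag (TRUE when all observations are identical and the F
#'   statistic is undefined).
#' @export
one_way_anova <- function(x, g) {
  d <- check_groups(x, g)
  if (stats::var(d$x) == 0) {
    return(list(statistic = NA_real_, df = c(nlevels(d$g) - 1,
                                             length(d$x) - nlevels(d$g)),
                p = NA_real_, n = d$n, degenerate = TRUE))
  }
  fit <- stats::aov(d$x ~ d$g)
  s <- summary(fit)[[1]]
  list(statistic = s$`F value`[1], df = s$Df, p = s$`Pr(>F)`[1], n = d$n,
       degenerate = FALSE)
}

#' Tukey HSD post hoc pairwise comparisons
#'
#' Studentized-range pairwise p-values at the pooled within-group variance,
#' following a one-way ANOVA.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with `pair`, `diff`, `p` and `significant`.
#' @export
tukey_hsd <- function(x, g, alpha = 0.05) {
  d <- check_groups(x, g)
  fit <- stats::aov(d$x ~ d$g)
  tk <- stats::TukeyHSD(fit)[[1]]
  tibble::tibble(pair = rownames(tk), diff = tk[, "diff"],
                 p = tk[, "p adj"], significant = tk[, "p adj"] < alpha)
}

#' Kruskal-Wallis rank-sum test
#'
#' Nonparametric omnibus comparison of mean ranks across groups, with the
#' standard tie correction. The fully degenerate case (every observation
#' identical) is reported as H = 0, p = 1 rather than an error.
#'
#' @inheritParams one_way_anova
#' @return A list with `statistic` (H), `df`, `p` and `n` per group.
#' @export
kruskal_wallis <- function(x, g) {
  d <- check_groups(x, g)
  if (length(unique(d$x)) == 1) {
    return(list(statistic = 0, df = nlevels(d$g) - 1, p = 1, n = d$n))
  }
  kt <- stats::kruskal.test(d$x, d$g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = d$n)
}

#' Nemenyi post hoc pairwise comparisons of ranked data
#'
#' All-pairs mean-rank comparison following a Kruskal-Wallis omnibus test.
#' Without ties the studentized-range distribution is used:
#' `q = |Ri - Rj| / sqrt(N(N+1)/12 (1/ni + 1/nj))`, `p = P(Q_{k,Inf} >= q
#' sqrt(2))`. With ties the chi-square variant applies: the squared
#' standardized difference is divided by the tie-correction factor
#' `C = 1 - sum(t^3 - t)/(N^3 - N)` and referred to chi-square with `k - 1`
#' degrees of freedom. The variant used is recorded in the output.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with `pair`, `mean_rank_diff`, `p`, `significant`, `method`.
#' @export
nemenyi_posthoc <- function(x, g, alpha = 0.05) {
  d <- check_groups(x, g)
  N <- length(d$x)
  k <- nlevels(d$g)
  r <- rank(d$x)
  rbar <- tapply(r, d$g, mean)
  n <- as.numeric(d$n)
  names(n) <- names(d$n)
  ties <- table(d$x)
  has_ties <- any(ties > 1)
  cmb <- utils::combn(levels(d$g), 2)
  out <- lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    dif <- abs(rbar[[a]] - rbar[[b]])
    se2 <- (N * (N + 1) / 12) * (1 / n[[a]] + 1 / n[[b]])
    if (has_ties) {
      C <- 1 - sum(ties^3 - ties) / (N^3 - N)
      if (C <= 0) {
        p <- 1 # all observations tied
      } else {
        p <- stats::pchisq(dif^2 / se2 / C, df = k - 1, lower.tail = FALSE)
      }
      method <- "chisq_ties"
    } else {
      p <- stats::ptukey(dif / sqrt(se2) * sqrt(2), nmeans = k, df = Inf,
                         lower.tail = FALSE)
      method <- "tukey"
    }
    tibble::tibble(pair = paste(a, b, sep = "-"),
                   mean_rank_diff = rbar[[a]] - rbar[[b]],
                   p = p, significant = p < alpha, method = method)
  })
  dplyr::bind_rows(out)
}

#' Per-exercise-minute group comparison under attrition
#'
#' At each exercise minute, restricts to subjects still exercising, runs a
#' Kruskal-Wallis test across the three constitutional groups within the
#' stratum, and on a significant omnibus result runs the Nemenyi post hoc
#' test. Pairwise outcomes are encoded as significance letters following the
#' figure convention: `a` = TE differs from SE, `b` = TE differs from SY,
#' `c` = SE differs from SY. Minutes where any group falls below `min_n`
#' subjects are reported untested; exercise times differ between subjects, so
#' late minutes thin out. No multiplicity correction is applied across
#' minutes.
#'
#' @param data Long tibble with columns `id`, `group`, `minute`, `value`.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum per-group n for a minute to be tested (default 2).
#' @param groups Group labels expected (default TE, SE, SY).
#' @return Tibble with one row per minute: per-group n, `H`, `p`, pairwise
#'   p-values `p_te_se`, `p_te_sy`, `p_se_sy`, `letters` and `tested`.
#' @export
timecourse_compare <- function(data, alpha = 0.05, min_n = 2,
                               groups = c("TE", "SE", "SY")) {
  stopifnot(all(c("id", "group", "minute", "value") %in% names(data)))
  unknown <- setdiff(unique(data$group), groups)
  if (length(unknown) > 0) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  minutes <- sort(unique(data$minute))
  rows <- lapply(minutes, function(m) {
    sub <- data[data$minute == m & is.finite(data$value), , drop = FALSE]
    n <- vapply(groups, function(gr) sum(sub$group == gr), integer(1))
    row <- tibble::tibble(minute = m, n_te = n[1], n_se = n[2], n_sy = n[3],
                          H = NA_real_, p = NA_real_,
                          p_te_se = NA_real_, p_te_sy = NA_real_,
                          p_se_sy = NA_real_, letters = "", tested = FALSE)
    if (any(n < min_n)) return(row)
    kw <- kruskal_wallis(sub$value, factor(sub$group, levels = groups))
    row$H <- kw$statistic; row$p <- kw$p; row$tested <- TRUE
    if (!is.na(kw$p) && kw$p < alpha) {
      nm <- nemenyi_posthoc(sub$value, factor(sub$group, levels = groups),
                            alpha = alpha)
      getp <- function(a, b) {
        hit <- nm$p[nm$pair %in% c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))]
        if (length(hit) == 0) NA_real_ else hit[1]
      }
      row$p_te_se <- getp("TE", "SE")
      row$p_te_sy <- getp("TE", "SY")
      row$p_se_sy <- getp("SE", "SY")
      lt <- c(if (!is.na(row$p_te_se) && row$p_te_se < alpha) "a",
              if (!is.na(row$p_te_sy) && row$p_te_sy < alpha) "b",
              if (!is.na(row$p_se_sy) && row$p_se_sy < alpha) "c")
      row$letters <- paste(lt, collapse = "")
    }
    row
  })
  dplyr::bind_rows(rows)
}
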