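# Shared fixtures: all synthetic, built in code.

make_breath <- function(t, vo2, rq = rep(0.85, length(t))) {
  tibble::tibble(t = t, vo2 = vo2, rq = rq)
}

# 20-s cadence exercise samples for a given number of minutes
cadence_times <- function(minutes) seq(20, minutes * 60, by = 20)

# a small but fully structured study spec for fast pipeline tests
small_cells <- function(n = 8L) {
  cells <- thermoex::default_cells()
  cells$n <- n
  cells
}

small_spec <- function(seed = 7, n = 8L, n_fail_scores = 6L,
                       n_fail_downstream = 2L) {
  thermoex::cohort_spec(seed = seed, cells = small_cells(n),
                        n_fail_scores = n_fail_scores,
                        n_fail_downstream = n_fail_downstream)
}

# permutation oracle for FWER-adjusted all-pairs mean-rank comparisons:
# adjusted p for pair (a, b) is the fraction of label permutations whose
# maximum standardized mean-rank difference reaches the observed one
perm_rank_maxstat_pvals <- function(x, g, B = 10000) {
  g <- factor(g)
  lev <- levels(g)
  n <- table(g)
  N <- length(x)
  cmb <- utils::combn(lev, 2)
  se <- sqrt((N * (N + 1) / 12) *
               (1 / as.numeric(n[cmb[1, ]]) + 1 / as.numeric(n[cmb[2, ]])))
  stat <- function(gg) {
    rb <- tapply(rank(x), gg, mean)
    abs(rb[cmb[1, ]] - rb[cmb[2, ]]) / se
  }
  obs <- stat(g)
  maxnull <- replicate(B, max(stat(sample(g))))
  vapply(obs, function(q) mean(maxnull >= q), numeric(1))
}

# permutation oracle for Tukey-style all-pairs mean comparisons
perm_mean_maxstat_pvals <- function(x, g, B = 10000) {
  g <- factor(g)
  lev <- levels(g)
  n <- table(g)
  cmb <- utils::combn(lev, 2)
  stat <- function(gg) {
    m <- tapply(x, gg, mean)
    v <- tapply(x, gg, var)
    s2 <- sum((n - 1) * v) / (length(x) - length(lev))
    abs(m[cmb[1, ]] - m[cmb[2, ]]) /
      sqrt(s2 * (1 / as.numeric(n[cmb[1, ]]) + 1 / as.numeric(n[cmb[2, ]])))
  }
  obs <- stat(g)
  maxnull <- replicate(B, max(stat(sample(g))))
  vapply(obs, function(q) mean(maxnull >= q), numeric(1))
}
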