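# Fixtures built in code and independent oracles used across the suite.

# A 4-study, 2-outcome dataset with mutually exclusive outcomes
# (e.g. caesarean vs instrumental vaginal birth).
fixture_exclusive <- function() {
  tables <- data.frame(
    study_id = rep(sprintf("s%d", 1:4), each = 2L),
    outcome_id = rep(c("caesarean", "instrumental"), 4L),
    events_t = c(30L, 20L, 45L, 25L, 18L, 12L, 60L, 35L),
    n_t = rep(c(100L, 150L, 80L, 220L), each = 2L),
    events_c = c(25L, 25L, 38L, 30L, 15L, 14L, 52L, 40L),
    n_c = rep(c(100L, 150L, 80L, 220L), each = 2L),
    stringsAsFactors = FALSE)
  relations <- data.frame(outcome_a = "caesarean", outcome_b = "instrumental",
                          relation = "mutually_exclusive",
                          stringsAsFactors = FALSE)
  meta_dataset(tables, relations)
}

# A 4-study dataset where one outcome is nested in the other.
fixture_subset <- function() {
  tables <- data.frame(
    study_id = rep(sprintf("s%d", 1:4), each = 2L),
    outcome_id = rep(c("death", "death_or_morbidity"), 4L),
    events_t = c(10L, 30L, 8L, 25L, 12L, 28L, 6L, 20L),
    n_t = rep(c(100L, 100L, 120L, 90L), each = 2L),
    events_c = c(12L, 32L, 10L, 28L, 15L, 33L, 9L, 24L),
    n_c = rep(c(100L, 100L, 120L, 90L), each = 2L),
    stringsAsFactors = FALSE)
  relations <- data.frame(outcome_a = "death",
                          outcome_b = "death_or_morbidity",
                          relation = "subset_a_of_b", stringsAsFactors = FALSE)
  meta_dataset(tables, relations)
}

# Degenerate dataset: two outcomes, two studies each, no study reports
# both — no information about any correlation.
fixture_disjoint <- function() {
  tables <- data.frame(
    study_id = c("s1", "s2", "s3", "s4"),
    outcome_id = c("a", "a", "b", "b"),
    events_t = c(12L, 20L, 15L, 25L),
    n_t = c(80L, 100L, 90L, 110L),
    events_c = c(18L, 25L, 10L, 30L),
    n_c = c(80L, 100L, 90L, 110L),
    stringsAsFactors = FALSE)
  meta_dataset(tables, outcome_ids = c("a", "b"))
}

# Monte-Carlo oracle for the within-study correlation of two log ORs,
# mutually exclusive outcomes: per-arm multinomial replicates at the
# plug-in probabilities, correlating the replicate log ORs.
mc_corr_exclusive <- function(a_t, b_t, n_t, a_c, b_c, n_c, reps = 1e5) {
  draw_arm <- function(a, b, n) {
    cells <- stats::rmultinom(reps, n, c(a / n, b / n, (n - a - b) / n))
    list(a = cells[1L, ], b = cells[2L, ])
  }
  lo <- function(x, n) {
    corr <- x == 0L | x == n
    log((x + 0.5 * corr) / (n - x + 0.5 * corr))
  }
  tr <- draw_arm(a_t, b_t, n_t)
  co <- draw_arm(a_c, b_c, n_c)
  yA <- lo(tr$a, n_t) - lo(co$a, n_c)
  yB <- lo(tr$b, n_t) - lo(co$b, n_c)
  stats::cor(yA, yB)
}

# Monte-Carlo oracle for nested outcomes: superset events binomial,
# subset events binomial within the superset events.
mc_corr_subset <- function(sub_t, sup_t, n_t, sub_c, sup_c, n_c, reps = 1e5) {
  draw_arm <- function(a_sub, a_sup, n) {
    sup <- stats::rbinom(reps, n, a_sup / n)
    sub <- stats::rbinom(reps, sup, a_sub / a_sup)
    list(sub = sub, sup = sup)
  }
  lo <- function(x, n) {
    corr <- x == 0L | x == n
    log((x + 0.5 * corr) / (n - x + 0.5 * corr))
  }
  tr <- draw_arm(sub_t, sup_t, n_t)
  co <- draw_arm(sub_c, sup_c, n_c)
  y_sub <- lo(tr$sub, n_t) - lo(co$sub, n_c)
  y_sup <- lo(tr$sup, n_t) - lo(co$sup, n_c)
  stats::cor(y_sub, y_sup)
}

# Brute-force grid-search REML oracle for the univariate random-effects
# model: profile restricted log-likelihood evaluated from its definition
# on a tau grid.
grid_reml_uvma <- function(y, v, tau_max = 2, step = 1e-4) {
  taus <- seq(0, tau_max, by = step)
  ll <- vapply(taus, function(tau) {
    w <- 1 / (v + tau^2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + tau^2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }, numeric(1L))
  i <- which.max(ll)
  w <- 1 / (v + taus[i]^2)
  list(tau = taus[i], mu = sum(w * y) / sum(w), ll = ll[i], ll_grid = ll)
}

# Restricted log-likelihood of a bivariate model evaluated from its
# definition (dense solve/determinant path, independent of the fitting
# engine): y_list/S_list per study over the observed outcome indices.
reml_ll_multivariate <- function(y_list, S_list, idx_list, Sigma, d = 2L) {
  A <- matrix(0, d, d)
  b <- numeric(d)
  quad <- 0
  logdet <- 0
  for (i in seq_along(y_list)) {
    idx <- idx_list[[i]]
    V <- S_list[[i]] + Sigma[idx, idx, drop = FALSE]
    Vi <- solve(V)
    logdet <- logdet + log(det(V))
    A[idx, idx] <- A[idx, idx] + Vi
    b[idx] <- b[idx] + Vi %*% y_list[[i]]
    quad <- quad + drop(t(y_list[[i]]) %*% Vi %*% y_list[[i]])
  }
  mu <- solve(A, b)
  -0.5 * (logdet + log(det(A)) + quad - sum(b * mu))
}

# Convenience: per-study pieces for a bivariate dataset fitted with
# within-study covariances.
study_pieces <- function(dataset, fixed_corr = NULL) {
  eff <- derive_effects(dataset)
  eff <- eff[!eff$missing, , drop = FALSE]
  wc <- assemble_within_cov(dataset, fixed_corr = fixed_corr)
  oids <- dataset$outcome_ids
  studies <- unique(eff$study_id)
  y_list <- list(); S_list <- list(); idx_list <- list()
  for (s in studies) {
    es <- eff[eff$study_id == s, , drop = FALSE]
    so <- intersect(oids, es$outcome_id)
    idx_list[[s]] <- match(so, oids)
    y_list[[s]] <- es$log_or[match(so, es$outcome_id)]
    S_list[[s]] <- wc[[s]]$matrix[so, so, drop = FALSE]
  }
  list(y = y_list, S = S_list, idx = idx_list, effects = eff)
}

# Truth object for the standard bivariate recovery scenario.
recovery_truth <- function(seed, k = 20L, rho = 0.7) {
  sim_truth(
    mu_true = c(subset_out = -0.7, superset_out = -0.4),
    tau_true = c(0.3, 0.3),
    rho_between_true = matrix(c(1, rho, rho, 1), 2L),
    baseline_risk = c(0.15, 0.35),
    relations = data.frame(outcome_a = "subset_out",
                           outcome_b = "superset_out",
                           relation = "subset_a_of_b",
                           stringsAsFactors = FALSE),
    k_studies = k, n_range = c(50L, 500L),
    missingness = list(type = "none"), seed = seed,
    outcome_ids = c("subset_out", "superset_out"))
}
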