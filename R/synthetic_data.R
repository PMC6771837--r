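#' Generating truth for a synthetic multi-outcome meta-analysis
#'
#' Describes the population a synthetic meta-analysis is drawn from:
#' true summary log odds ratios, between-study heterogeneity and
#' correlation of the study-level true effects, control-arm baseline
#' risks, the structural relations between outcomes, study sizes, and the
#' missing-outcome mechanism. Random study effects act on the
#' log-odds-ratio contrast applied to a fixed control-arm risk.
#'
#' @param mu_true numeric vector of true summary log ORs (one per
#'   outcome).
#' @param tau_true non-negative vector of between-study SDs.
#' @param rho_between_true between-study correlation matrix (PSD).
#' @param baseline_risk control-arm event probabilities in (0,1); for a
#'   subset relation the subset's baseline must not exceed the
#'   superset's, and mutually exclusive outcomes' baselines must sum
#'   below 1.
#' @param relations optional data.frame (`outcome_a`, `outcome_b`,
#'   `relation`) as in [meta_dataset()].
#' @param k_studies number of studies.
#' @param n_range length-2 integer vector: min/max per-arm sample size
#'   (one size per study, used in both arms).
#' @param missingness list describing the missing-outcome mechanism:
#'   `list(type = "none")`, `list(type = "mcar", p, outcomes = NULL)`
#'   (outcome-study cells deleted completely at random), or
#'   `list(type = "selective", outcomes, threshold = 0.05, prob = 0.8)`
#'   (significance-driven selective reporting, see
#'   [apply_selective_reporting()]).
#' @param seed integer seed; one seed drives the whole generation.
#' @param outcome_ids optional outcome names (default `o1`, `o2`, ...).
#' @param report_pattern optional named list (by outcome id) of study
#'   indices that structurally report each outcome, applied before the
#'   stochastic missingness mechanism.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(mu_true, tau_true, rho_between_true, baseline_risk,
                      relations = NULL, k_studies, n_range,
                      missingness = list(type = "none"), seed = 1L,
                      outcome_ids = NULL, report_pattern = NULL) {
  d <- length(mu_true)
  if (is.null(outcome_ids)) outcome_ids <- paste0("o", seq_len(d))
  stopifnot(length(tau_true) == d, length(baseline_risk) == d,
            all(tau_true >= 0), all(baseline_risk > 0 & baseline_risk < 1),
            k_studies >= 1L, length(n_range) == 2L, n_range[1L] >= 1L,
            n_range[2L] >= n_range[1L])
  rho_between_true <- as.matrix(rho_between_true)
  stopifnot(nrow(rho_between_true) == d, ncol(rho_between_true) == d)
  ev <- eigen((rho_between_true + t(rho_between_true)) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("rho_between_true is not positive semi-definite")
  relations <- validate_relations(relations, outcome_ids)
  names(mu_true) <- names(tau_true) <- names(baseline_risk) <- outcome_ids
  for (i in seq_len(nrow(relations))) {
    a <- relations$outcome_a[i]; b <- relations$outcome_b[i]
    r <- relations$relation[i]
    if (r == "subset_a_of_b" && baseline_risk[a] > baseline_risk[b]) {
      stop("subset outcome's baseline risk exceeds its superset's")
    }
    if (r == "subset_b_of_a" && baseline_risk[b] > baseline_risk[a]) {
      stop("subset outcome's baseline risk exceeds its superset's")
    }
    if (r == "mutually_exclusive" &&
        baseline_risk[a] + baseline_risk[b] >= 1) {
      stop("mutually exclusive outcomes' baseline risks sum to 1 or more")
    }
  }
  if (!missingness$type %in% c("none", "mcar", "selective")) {
    stop("missingness$type must be none, mcar or selective")
  }
  structure(list(mu_true = mu_true, tau_true = tau_true,
                 rho_between_true = rho_between_true,
                 baseline_risk = baseline_risk, relations = relations,
                 k_studies = as.integer(k_studies),
                 n_range = as.integer(n_range), missingness = missingness,
                 seed = as.integer(seed), outcome_ids = outcome_ids,
                 report_pattern = report_pattern),
            class = "sim_truth")
}

# Partition outcomes into generation groups: a connected set of mutually
# exclusive outcomes (multinomial cells), a subset chain ordered superset
# to subset (nested binomials), or singletons (independent binomials).
relation_groups <- function(truth) {
  d <- length(truth$outcome_ids)
  oid <- truth$outcome_ids
  rel <- truth$relations
  parent <- seq_len(d)
  for (i in seq_len(nrow(rel))) {
    if (rel$relation[i] == "unrelated") next
    a <- match(rel$outcome_a[i], oid); b <- match(rel$outcome_b[i], oid)
    ra <- find_root(parent, a); rb <- find_root(parent, b)
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(d), function(i) find_root(parent, i), integer(1L))
  groups <- split(seq_len(d), roots)
  lapply(groups, function(g) {
    if (length(g) == 1L) return(list(type = "single", members = g))
    sub <- rel[rel$outcome_a %in% oid[g] & rel$outcome_b %in% oid[g] &
                 rel$relation != "unrelated", , drop = FALSE]
    types <- unique(sub$relation)
    if (all(types == "mutually_exclusive")) {
      return(list(type = "exclusive", members = g))
    }
    if (all(types %in% c("subset_a_of_b", "subset_b_of_a"))) {
      # order superset -> subset via transitive closure of 'is subset of'
      sup_of <- matrix(FALSE, length(g), length(g))
      gi <- function(o) match(match(o, oid), g)
      for (i in seq_len(nrow(sub))) {
        a <- gi(sub$outcome_a[i]); b <- gi(sub$outcome_b[i])
        if (sub$relation[i] == "subset_a_of_b") sup_of[a, b] <- TRUE else sup_of[b, a] <- TRUE
      }
      for (m in seq_along(g)) {
        sup_of <- sup_of | (sup_of %*% sup_of > 0)
      }
      n_sup <- rowSums(sup_of)
      if (any(duplicated(n_sup))) {
        stop("subset relations within a group must form a chain for generation")
      }
      return(list(type = "chain", members = g[order(n_sup)]))
    }
    stop("a relation group mixes mutually exclusive and subset relations; generation is not defined for such mixtures")
  })
}

find_root <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Draw one arm's event counts for all outcomes, respecting the relation
# structure. p is the vector of per-outcome event probabilities.
draw_arm <- function(n, p, groups) {
  events <- integer(length(p))
  for (g in groups) {
    m <- g$members
    if (g$type == "single") {
      events[m] <- rbinom(1L, n, p[m])
    } else if (g$type == "exclusive") {
      ps <- p[m]
      tot <- sum(ps)
      if (tot >= 1) ps <- ps * (0.99 / tot) # keep a non-event cell
      cells <- as.integer(stats::rmultinom(1L, n, c(ps, 1 - sum(ps))))
      events[m] <- cells[seq_along(m)]
    } else { # chain, ordered superset -> subset
      a_parent <- rbinom(1L, n, p[m[1L]])
      events[m[1L]] <- a_parent
      for (j in seq_along(m)[-1L]) {
        cond <- if (p[m[j - 1L]] > 0) min(1, p[m[j]] / p[m[j - 1L]]) else 0
        a_parent <- if (a_parent > 0) rbinom(1L, a_parent, cond) else 0L
        events[m[j]] <- a_parent
      }
    }
  }
  events
}

#' Generate a synthetic multi-outcome meta-analysis dataset
#'
#' Per study: a per-arm size is drawn uniformly from `n_range`; the
#' study's true log ORs are drawn from
#' \eqn{N(\mu, D\,\rho_B\,D)} with \eqn{D = diag(\tau)}; control-arm event
#' probabilities are the baseline risks and treatment-arm probabilities
#' shift the baseline by the study's true log OR on the logit scale;
#' event counts are drawn respecting the structural relations
#' (multinomial cells for mutually exclusive groups, nested binomials for
#' subset chains, independent binomials otherwise); the structural
#' reporting pattern and the stochastic missingness mechanism are then
#' applied. The same seed always yields the identical dataset.
#'
#' @param truth a [sim_truth].
#' @return object of class `sim_result`: `dataset` (a validated
#'   [meta_dataset]), `truth`, and `per_study_true_effects` (k x d matrix
#'   of the study-level true log ORs).
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  d <- length(truth$outcome_ids)
  k <- truth$k_studies
  groups <- relation_groups(truth)

  n_arm <- sample(seq(truth$n_range[1L], truth$n_range[2L]), k, replace = TRUE)
  Sigma <- diag(truth$tau_true, d) %*% truth$rho_between_true %*%
    diag(truth$tau_true, d)
  Z <- matrix(rnorm(k * d), k, d)
  ch <- chol(Sigma + diag(1e-12, d))
  theta <- sweep(Z %*% ch, 2L, truth$mu_true, `+`)
  colnames(theta) <- truth$outcome_ids

  p0 <- truth$baseline_risk
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    p1 <- stats::plogis(stats::qlogis(p0) + theta[i, ])
    ev_t <- draw_arm(n_arm[i], p1, groups)
    ev_c <- draw_arm(n_arm[i], p0, groups)
    rows[[i]] <- data.frame(
      study_id = sprintf("s%02d", i), outcome_id = truth$outcome_ids,
      events_t = ev_t, n_t = n_arm[i], events_c = ev_c, n_c = n_arm[i],
      stringsAsFactors = FALSE)
  }
  tables <- do.call(rbind, rows)

  if (!is.null(truth$report_pattern)) {
    keep <- rep(TRUE, nrow(tables))
    study_num <- as.integer(sub("^s", "", tables$study_id))
    for (oid in names(truth$report_pattern)) {
      sel <- tables$outcome_id == oid
      keep[sel] <- study_num[sel] %in% truth$report_pattern[[oid]]
    }
    tables <- tables[keep, , drop = FALSE]
  }

  ds <- meta_dataset(tables, truth$relations, truth$outcome_ids)

  mis <- truth$missingness
  if (mis$type == "mcar") {
    target <- mis$outcomes %||% truth$outcome_ids
    sel <- which(ds$tables$outcome_id %in% target)
    drop <- sel[runif(length(sel)) < mis$p]
    if (length(drop) > 0L) {
      ds <- meta_dataset(ds$tables[-drop, , drop = FALSE], truth$relations,
                         truth$outcome_ids)
    }
  } else if (mis$type == "selective") {
    ds <- apply_selective_reporting(
      ds, outcomes = mis$outcomes,
      threshold = mis$threshold %||% 0.05,
      prob = mis$prob %||% 0.8)
  }

  structure(list(dataset = ds, truth = truth,
                 per_study_true_effects = theta),
            class = "sim_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Significance-driven selective outcome reporting
#'
#' Emulates the missingness mechanism behind small-study effects: for the
#' designated outcomes, a study's result is deleted with probability
#' `prob` (default 0.8) when its two-sided Wald p-value exceeds
#' `threshold` (default 0.05) *and* its per-arm size is below the median
#' per-arm size of the dataset's studies — small, non-significant results
#' go unreported while small significant ones survive, skewing the
#' reported evidence. Deletions are logged in the attribute
#' `"deletions"`. Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param dataset a [meta_dataset] with computable per-study effects.
#' @param outcomes outcome ids subject to selective reporting.
#' @param threshold p-value threshold above which a result is at risk.
#' @param prob deletion probability for an at-risk result.
#' @return the thinned [meta_dataset], with attribute `"deletions"`.
#' @export
apply_selective_reporting <- function(dataset, outcomes, threshold = 0.05,
                                      prob = 0.8) {
  stopifnot(inherits(dataset, "meta_dataset"))
  eff <- derive_effects(dataset)
  tab <- dataset$tables
  study_n <- tapply(tab$n_t, tab$study_id, max)
  med_n <- median(study_n)
  drop <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!tab$outcome_id[i] %in% outcomes) next
    e <- eff[eff$study_id == tab$study_id[i] &
               eff$outcome_id == tab$outcome_id[i], ]
    if (e$missing) next
    pval <- 2 * pnorm(-abs(e$log_or) / sqrt(e$var))
    if (pval > threshold && tab$n_t[i] < med_n && runif(1L) < prob) {
      drop[i] <- TRUE
    }
  }
  out <- meta_dataset(tab[!drop, , drop = FALSE], dataset$relations,
                      dataset$outcome_ids)
  attr(out, "deletions") <- tab[drop, c("study_id", "outcome_id"), drop = FALSE]
  out
}

#' Packaged scenario emulating a review with selective reporting
#'
#' A four-outcome meta-analysis patterned on a review of interventions
#' against nausea and vomiting around caesarean section: 10 studies in
#' all, outcome 1 structurally reported by 8 studies, outcome 3 by 4 and
#' outcome 4 by 5; outcomes are clinically related but not structurally
#' so (no analytic within-study correlations), with strong between-study
#' correlation of the true effects (0.9) and substantial heterogeneity
#' (between-study SD 0.8, the scale the emulated review itself
#' exhibited); outcome 2 is subject to significance-driven selective
#' reporting (small non-significant results always withheld), which
#' induces small-study effects and biases its univariate summary away
#' from the null. A multivariate model can partially correct that bias by
#' borrowing strength from the completely reported correlated outcomes —
#' high heterogeneity matters here because it equalizes study weights, so
#' withholding small studies actually moves the pooled estimate.
#'
#' @param seed integer seed.
#' @return a [sim_truth] ready for [generate_dataset()].
#' @export
review7_scenario <- function(seed = 71L) {
  rho <- matrix(0.9, 4L, 4L); diag(rho) <- 1
  sim_truth(
    mu_true = log(c(0.40, 0.55, 0.25, 0.30)),
    tau_true = rep(0.8, 4L),
    rho_between_true = rho,
    baseline_risk = c(0.35, 0.30, 0.30, 0.35),
    relations = NULL,
    k_studies = 10L,
    n_range = c(25L, 400L),
    missingness = list(type = "selective", outcomes = "vomiting_intraop",
                       threshold = 0.05, prob = 1),
    seed = seed,
    outcome_ids = c("nausea_intraop", "vomiting_intraop", "nausea_postop",
                    "vomiting_postop"),
    report_pattern = list(
      nausea_intraop = 1:8,
      vomiting_intraop = 1:8,
      nausea_postop = 7:10,
      vomiting_postop = 6:10))
}

#' Preset grid of simulation scenarios
#'
#' The standard bivariate scenario family used for calibration and
#' recovery checks: a subset-structured outcome pair (baseline risks 0.15
#' within 0.35, true log ORs -0.7 and -0.4) crossed over numbers of
#' studies, heterogeneity levels, between-study correlations and
#' missingness mechanisms.
#'
#' @return data.frame of preset parameter combinations with a `preset_id`
#'   column.
#' @export
sim_preset_grid <- function() {
  grid <- expand.grid(k = c(5L, 10L, 20L, 50L), tau = c(0, 0.3, 0.6),
                      rho = c(0, 0.5, 0.9),
                      missingness = c("none", "mcar", "selective"),
                      stringsAsFactors = FALSE)
  grid$preset_id <- sprintf("k%d_tau%s_rho%s_%s", grid$k, grid$tau, grid$rho,
                            grid$missingness)
  grid
}

#' Build the truth object for one preset
#'
#' @param preset_id a `preset_id` from [sim_preset_grid()], or its row.
#' @param seed integer seed.
#' @return a [sim_truth].
#' @export
sim_preset <- function(preset_id, seed = 1L) {
  grid <- sim_preset_grid()
  row <- grid[grid$preset_id == preset_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown preset_id: ", preset_id)
  mis <- switch(row$missingness,
                none = list(type = "none"),
                mcar = list(type = "mcar", p = 0.3, outcomes = "subset_out"),
                selective = list(type = "selective", outcomes = "subset_out",
                                 threshold = 0.05, prob = 0.8))
  sim_truth(
    mu_true = c(subset_out = -0.7, superset_out = -0.4),
    tau_true = rep(row$tau, 2L),
    rho_between_true = matrix(c(1, row$rho, row$rho, 1), 2L),
    baseline_risk = c(0.15, 0.35),
    relations = data.frame(outcome_a = "subset_out",
                           outcome_b = "superset_out",
                           relation = "subset_a_of_b",
                           stringsAsFactors = FALSE),
    k_studies = row$k, n_range = c(50L, 500L), missingness = mis,
    seed = seed, outcome_ids = c("subset_out", "superset_out"))
}
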