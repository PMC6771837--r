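opts_fast <- function(seed = 1L, ...) {
  fit_options(seed = seed, objective_tolerance = 1e-12, ...)
}

test_that("with all correlations fixed at zero the joint likelihood factorizes into the univariate fits", {
  res <- generate_dataset(recovery_truth(seed = 101))
  eff <- derive_effects(res$dataset)
  oids <- res$dataset$outcome_ids
  R0 <- diag(2L); dimnames(R0) <- list(oids, oids)
  # within-study correlations fixed at zero (diagonal S) and between-study
  # correlation fixed at zero: the joint likelihood is block diagonal
  wc0 <- assemble_within_cov(meta_dataset(res$dataset$tables,
                                          outcome_ids = oids),
                             fixed_corr = R0)
  h <- fit_hierarchical(eff, wc0, opts_fast(fix_correlations = R0))
  r <- fit_riley(eff, opts_fast(fix_correlations = R0))
  expect_equal(r$model, "riley_fixed")
  for (oid in oids) {
    u <- fit_uvma(eff, outcome_id = oid)
    expect_equal(unname(h$mu[oid]), u$mu, tolerance = 1e-6)
    expect_equal(unname(h$tau[oid]), u$tau, tolerance = 1e-6)
    expect_equal(unname(r$mu[oid]), u$mu, tolerance = 1e-6)
    expect_equal(unname(r$tau[oid]), u$tau, tolerance = 1e-6)
  }
})

test_that("the profiled between-study correlation matches a brute-force grid search", {
  ds <- fixture_subset()
  pieces <- study_pieces(ds)
  tauF <- c(death = 0.25, death_or_morbidity = 0.25)
  f <- fit_hierarchical(pieces$effects, assemble_within_cov(ds),
                        opts_fast(fix_tau = tauF))
  expect_equal(f$status, "converged")
  # independent dense-algebra REML surface over rho
  rhos <- seq(-0.999, 0.999, by = 2e-3)
  ll <- vapply(rhos, function(rho) {
    Sigma <- diag(tauF) %*% matrix(c(1, rho, rho, 1), 2L) %*% diag(tauF)
    reml_ll_multivariate(pieces$y, pieces$S, pieces$idx, Sigma)
  }, numeric(1L))
  rho_hat <- f$rho_between[1L, 2L]
  expect_equal(rho_hat, rhos[which.max(ll)], tolerance = 5e-3)
  expect_gte(f$loglik, max(ll) - 1e-6)
})

test_that("hierarchical estimates agree with an independent multivariate REML implementation", {
  skip_if_not_installed("metafor")
  res <- generate_dataset(recovery_truth(seed = 55))
  ds <- res$dataset
  eff <- derive_effects(ds)
  wc <- assemble_within_cov(ds)
  f <- fit_hierarchical(eff, wc, opts_fast())
  expect_equal(f$status, "converged")

  long <- eff[!eff$missing, ]
  Vlist <- lapply(unique(long$study_id), function(s) {
    wc[[s]]$matrix[long$outcome_id[long$study_id == s],
                   long$outcome_id[long$study_id == s], drop = FALSE]
  })
  m <- metafor::rma.mv(yi = long$log_or, V = Matrix::bdiag(Vlist),
                       mods = ~ 0 + outcome_id, data = long,
                       random = ~ outcome_id | study_id, struct = "UN",
                       method = "REML", sparse = FALSE)
  mu_ref <- setNames(as.numeric(m$beta),
                     sub("^outcome_id", "", rownames(m$beta)))
  for (oid in ds$outcome_ids) {
    expect_equal(unname(f$mu[oid]), unname(mu_ref[oid]), tolerance = 1e-3)
  }
  expect_equal(unname(f$tau), sqrt(m$tau2), tolerance = 1e-2)
  expect_equal(f$rho_between[1L, 2L], m$rho, tolerance = 1e-2)
})

test_that("Riley model with correlation fixed at zero reproduces the univariate fits", {
  res <- generate_dataset(recovery_truth(seed = 77))
  eff <- derive_effects(res$dataset)
  oids <- res$dataset$outcome_ids
  R0 <- diag(2L); dimnames(R0) <- list(oids, oids)
  r <- fit_riley(eff, opts_fast(fix_correlations = R0))
  for (oid in oids) {
    u <- fit_uvma(eff, outcome_id = oid)
    expect_equal(unname(r$mu[oid]), u$mu, tolerance = 1e-6)
    expect_equal(unname(r$tau[oid]), u$tau, tolerance = 1e-6)
  }
})

test_that("strongly correlated outcomes may hit the correlation boundary, flagged but converged", {
  # perfectly correlated true effects: the between-study correlation is
  # estimated on the +1 boundary yet the fit is a valid converged maximum
  truth <- sim_truth(
    mu_true = c(a = -0.5, b = -0.3), tau_true = c(0.4, 0.4),
    rho_between_true = matrix(1, 2L, 2L), baseline_risk = c(0.25, 0.3),
    relations = data.frame(outcome_a = "a", outcome_b = "b",
                           relation = "mutually_exclusive"),
    k_studies = 8L, n_range = c(100L, 400L), seed = 1L,
    outcome_ids = c("a", "b"))
  res <- generate_dataset(truth)
  eff <- derive_effects(res$dataset)
  f <- fit_hierarchical(eff, assemble_within_cov(res$dataset),
                        fit_options(seed = 1L))
  expect_equal(f$status, "converged")
  expect_true(f$boundary_flags[1L, 2L])
  expect_equal(abs(f$rho_between[1L, 2L]), 1)
})

test_that("identical seeds and options give identical fits", {
  res <- generate_dataset(recovery_truth(seed = 13))
  eff <- derive_effects(res$dataset)
  wc <- assemble_within_cov(res$dataset)
  f1 <- fit_hierarchical(eff, wc, opts_fast(seed = 5))
  f2 <- fit_hierarchical(eff, wc, opts_fast(seed = 5))
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$tau, f2$tau)
  expect_identical(f1$status, f2$status)
})

test_that("the likelihood is invariant to reordering outcomes and studies", {
  res <- generate_dataset(recovery_truth(seed = 21))
  ds <- res$dataset
  eff <- derive_effects(ds)
  wc <- assemble_within_cov(ds)
  f <- fit_hierarchical(eff, wc, opts_fast())
  # outcome order flipped
  f_rev <- fit_hierarchical(eff, wc, opts_fast(),
                            outcome_ids = rev(ds$outcome_ids))
  expect_equal(f$loglik, f_rev$loglik, tolerance = 1e-5)
  expect_equal(unname(f$mu[ds$outcome_ids]),
               unname(f_rev$mu[ds$outcome_ids]), tolerance = 1e-4)
  # study order shuffled
  set.seed(1)
  tab <- ds$tables[sample.int(nrow(ds$tables)), ]
  ds2 <- meta_dataset(tab, ds$relations, ds$outcome_ids)
  f_shuf <- fit_hierarchical(derive_effects(ds2), assemble_within_cov(ds2),
                             opts_fast())
  expect_equal(f$loglik, f_shuf$loglik, tolerance = 1e-6)
})

test_that("disjoint reporting with two studies per outcome is a reported convergence failure, not an error", {
  ds <- fixture_disjoint()
  eff <- derive_effects(ds)
  r <- expect_no_error(fit_riley(eff, opts_fast()))
  expect_equal(r$status, "failed_convergence")
  expect_match(r$diagnostics$message, "not identifiable")
  h <- expect_no_error(fit_hierarchical(eff, assemble_within_cov(ds),
                                        opts_fast()))
  expect_equal(h$status, "failed_convergence")
})

test_that("convergence policy accepts a clean optimum and rejects a saddle", {
  quad <- function(x) sum(x^2)
  tr <- list(par = c(0, 0), value = 0, convergence = 0L, objective = quad,
             lower = c(-5, -5), upper = c(5, 5))
  pol <- convergence_policy(tr, fit_options())
  expect_equal(pol$status, "converged")
  saddle <- function(x) x[1L]^2 - x[2L]^2
  tr$objective <- saddle
  pol <- convergence_policy(tr, fit_options())
  expect_equal(pol$status, "failed_convergence")
  # away from a stationary point the gradient check fails
  tr2 <- list(par = c(1, 1), value = 2, convergence = 0L, objective = quad,
              lower = c(-5, -5), upper = c(5, 5))
  pol <- convergence_policy(tr2, fit_options())
  expect_equal(pol$status, "failed_convergence")
})

test_that("borrowing strength under missingness never inflates the fixed-parameter standard error", {
  # small version of the missing-data efficiency property: variance
  # parameters held at truth, outcome 2 thinned at random
  rho <- 0.8
  R <- matrix(c(1, rho, rho, 1), 2L)
  truth <- sim_truth(mu_true = c(a = -0.5, b = -0.3), tau_true = c(0.3, 0.3),
                     rho_between_true = R, baseline_risk = c(0.3, 0.35),
                     k_studies = 16L, n_range = c(50L, 400L),
                     missingness = list(type = "mcar", p = 0.5, outcomes = "b"),
                     seed = 404L, outcome_ids = c("a", "b"))
  res <- generate_dataset(truth)
  eff <- derive_effects(res$dataset)
  dimnames(R) <- list(c("a", "b"), c("a", "b"))
  fw <- matrix(c(1, rho, rho, 1), 2L, dimnames = dimnames(R))
  wc <- assemble_within_cov(res$dataset, fixed_corr = fw)
  tauF <- c(a = 0.3, b = 0.3)
  mv <- fit_hierarchical(eff, wc, opts_fast(fix_correlations = R,
                                            fix_tau = tauF))
  uv <- fit_uvma(eff, outcome_id = "b", fixed_tau2 = 0.09)
  expect_equal(mv$status, "converged")
  expect_lte(mv$se_mu[["b"]], uv$se_mu + 1e-10)
})

test_that("fit_all_pairs fits every pair plus the full model and isolates failures", {
  # three outcomes: a subset pair (analytic correlations) and an
  # unrelated third outcome (Riley route)
  truth <- sim_truth(
    mu_true = c(sub = -0.6, sup = -0.3, other = 0.2),
    tau_true = c(0.2, 0.2, 0.2),
    rho_between_true = matrix(c(1, .5, .3, .5, 1, .3, .3, .3, 1), 3L),
    baseline_risk = c(0.15, 0.35, 0.25),
    relations = data.frame(outcome_a = "sub", outcome_b = "sup",
                           relation = "subset_a_of_b"),
    k_studies = 12L, n_range = c(80L, 400L), seed = 66L,
    outcome_ids = c("sub", "sup", "other"))
  ds <- generate_dataset(truth)$dataset
  out <- fit_all_pairs(ds, opts_fast())
  expect_length(out$pairs, 3L)
  expect_false(is.null(out$full))
  expect_equal(out$pairs[["bivariate(1,2)"]]$model, "hierarchical")
  expect_equal(out$pairs[["bivariate(1,3)"]]$model, "riley")
  expect_equal(out$pairs[["bivariate(2,3)"]]$model, "riley")
  expect_equal(out$full$model, "riley")

  # a degenerate pair fails alone without aborting the others
  tab <- rbind(ds$tables,
               data.frame(study_id = c("x1", "x2"), outcome_id = "lone",
                          events_t = c(5L, 8L), n_t = c(50L, 60L),
                          events_c = c(7L, 6L), n_c = c(50L, 60L)))
  ds2 <- meta_dataset(tab, ds$relations,
                      c(ds$outcome_ids, "lone"))
  out2 <- fit_all_pairs(ds2, opts_fast(), min_studies = 2L)
  statuses <- vapply(out2$pairs, `[[`, character(1L), "status")
  expect_true(any(statuses == "failed_convergence"))
  expect_true(any(statuses == "converged"))
})
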