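test_that("generated tables always satisfy the structural invariants", {
  # exclusive pair, subset chain and unrelated outcome in one dataset,
  # over several seeds: validation inside meta_dataset() must never fire
  for (s in 1:10) {
    truth <- sim_truth(
      mu_true = c(va = -0.2, cs = 0.3, death = -0.5, composite = -0.3),
      tau_true = c(0.2, 0.2, 0.3, 0.3),
      rho_between_true = diag(4L) * 0.5 + 0.5,
      baseline_risk = c(0.45, 0.3, 0.1, 0.3),
      relations = rbind(
        data.frame(outcome_a = "va", outcome_b = "cs",
                   relation = "mutually_exclusive"),
        data.frame(outcome_a = "death", outcome_b = "composite",
                   relation = "subset_a_of_b")),
      k_studies = 15L, n_range = c(20L, 200L), seed = 100L + s,
      outcome_ids = c("va", "cs", "death", "composite"))
    res <- generate_dataset(truth)
    expect_s3_class(res$dataset, "meta_dataset")
    tab <- res$dataset$tables
    wide_t <- tapply(tab$events_t, list(tab$study_id, tab$outcome_id), identity)
    expect_true(all(wide_t[, "death"] <= wide_t[, "composite"]))
    n_by_study <- tapply(tab$n_t, tab$study_id, max)
    expect_true(all(wide_t[, "va"] + wide_t[, "cs"] <= n_by_study))
    expect_equal(dim(res$per_study_true_effects), c(15L, 4L))
  }
})

test_that("inconsistent relation and baseline risk configurations are rejected", {
  expect_error(sim_truth(
    mu_true = c(a = 0, b = 0), tau_true = c(0.1, 0.1),
    rho_between_true = diag(2L), baseline_risk = c(0.4, 0.2),
    relations = data.frame(outcome_a = "a", outcome_b = "b",
                           relation = "subset_a_of_b"),
    k_studies = 5L, n_range = c(50L, 100L), outcome_ids = c("a", "b")),
    "baseline risk exceeds")
  expect_error(sim_truth(
    mu_true = c(a = 0, b = 0), tau_true = c(0.1, 0.1),
    rho_between_true = diag(2L), baseline_risk = c(0.6, 0.5),
    relations = data.frame(outcome_a = "a", outcome_b = "b",
                           relation = "mutually_exclusive"),
    k_studies = 5L, n_range = c(50L, 100L), outcome_ids = c("a", "b")),
    "sum to 1 or more")
})

test_that("the same seed reproduces the identical dataset", {
  t1 <- review7_scenario(seed = 3L)
  r1 <- generate_dataset(t1)
  r2 <- generate_dataset(review7_scenario(seed = 3L))
  expect_identical(r1$dataset$tables, r2$dataset$tables)
  expect_identical(r1$per_study_true_effects, r2$per_study_true_effects)
  r3 <- generate_dataset(review7_scenario(seed = 4L))
  expect_false(identical(r1$dataset$tables, r3$dataset$tables))
})

test_that("with no heterogeneity and huge arms each study's log OR approaches the truth", {
  truth <- sim_truth(mu_true = c(out = -0.35), tau_true = 0,
                     rho_between_true = matrix(1, 1L, 1L),
                     baseline_risk = 0.3, k_studies = 5L,
                     n_range = c(1000000L, 1000000L), seed = 8L,
                     outcome_ids = "out")
  eff <- derive_effects(generate_dataset(truth)$dataset)
  expect_true(all(abs(eff$log_or - (-0.35)) < 0.02))
})

test_that("the empirical between-study variance of the true effects converges to tau squared", {
  truth <- sim_truth(mu_true = c(a = -0.5, b = -0.2), tau_true = c(0.4, 0.25),
                     rho_between_true = matrix(c(1, .6, .6, 1), 2L),
                     baseline_risk = c(0.2, 0.3), k_studies = 2000L,
                     n_range = c(50L, 100L), seed = 15L,
                     outcome_ids = c("a", "b"))
  theta <- generate_dataset(truth)$per_study_true_effects
  expect_equal(var(theta[, "a"]) / 0.4^2, 1, tolerance = 0.05)
  expect_equal(var(theta[, "b"]) / 0.25^2, 1, tolerance = 0.05)
  expect_equal(cor(theta[, "a"], theta[, "b"]), 0.6, tolerance = 0.05)
})

test_that("the generator's cross-replicate correlation reproduces the analytic subset value", {
  # one fixed study configuration replicated many times: the empirical
  # correlation of the two log ORs matches the delta-method formula
  n <- 200L
  p_sup <- 0.35; p_sub <- 0.15
  reps <- 4e4
  set.seed(77)
  a_sup_t <- rbinom(reps, n, p_sup)
  a_sub_t <- rbinom(reps, a_sup_t, p_sub / p_sup)
  a_sup_c <- rbinom(reps, n, p_sup)
  a_sub_c <- rbinom(reps, a_sup_c, p_sub / p_sup)
  lo <- function(x) log((x + 0.5 * (x == 0 | x == n)) /
                          (n - x + 0.5 * (x == 0 | x == n)))
  emp <- cor(lo(a_sub_t) - lo(a_sub_c), lo(a_sup_t) - lo(a_sup_c))
  ana <- corr_subset(
    list(events_t = round(n * p_sub), n_t = n, events_c = round(n * p_sub), n_c = n),
    list(events_t = round(n * p_sup), n_t = n, events_c = round(n * p_sup), n_c = n))
  expect_equal(emp, ana$rho_w, tolerance = 0.02)
})

test_that("selective reporting deletes only small non-significant results and logs them", {
  truth <- recovery_truth(seed = 5L, k = 30L)
  ds <- generate_dataset(truth)$dataset
  eff <- derive_effects(ds)
  set.seed(5)
  thin <- apply_selective_reporting(ds, outcomes = "subset_out")
  del <- attr(thin, "deletions")
  expect_true(all(del$outcome_id == "subset_out"))
  med_n <- median(tapply(ds$tables$n_t, ds$tables$study_id, max))
  for (i in seq_len(nrow(del))) {
    e <- eff[eff$study_id == del$study_id[i] &
               eff$outcome_id == del$outcome_id[i], ]
    pval <- 2 * pnorm(-abs(e$log_or) / sqrt(e$var))
    expect_gt(pval, 0.05)
    n_i <- ds$tables$n_t[ds$tables$study_id == del$study_id[i]][1L]
    expect_lt(n_i, med_n)
  }
  # all-significant datasets lose nothing
  eff_sig <- ds
  set.seed(6)
  strong <- sim_truth(mu_true = c(out = -2.5), tau_true = 0.05,
                      rho_between_true = matrix(1, 1L, 1L),
                      baseline_risk = 0.4, k_studies = 8L,
                      n_range = c(400L, 600L), seed = 9L, outcome_ids = "out")
  ds_sig <- generate_dataset(strong)$dataset
  thin_sig <- apply_selective_reporting(ds_sig, outcomes = "out")
  expect_equal(nrow(thin_sig$tables), nrow(ds_sig$tables))
  # mechanism "none" leaves the dataset untouched
  truth_none <- recovery_truth(seed = 5L)
  expect_identical(generate_dataset(truth_none)$dataset$tables,
                   generate_dataset(truth_none)$dataset$tables)
})

test_that("the packaged selective-reporting scenario reproduces its reporting pattern and runs end-to-end", {
  res <- generate_dataset(review7_scenario(seed = 2L))
  tab <- res$dataset$tables
  counts <- table(tab$outcome_id)
  expect_equal(unname(counts[["nausea_intraop"]]), 8L)
  expect_equal(unname(counts[["nausea_postop"]]), 4L)
  expect_equal(unname(counts[["vomiting_postop"]]), 5L)
  expect_lte(unname(counts[["vomiting_intraop"]]), 8L)
  # smoke: univariate fits plus one bivariate Riley fit
  eff <- derive_effects(res$dataset)
  uv <- fit_uvma_all(res$dataset)
  expect_gte(length(uv), 2L)
  rb <- fit_riley(eff, fit_options(seed = 1L),
                  outcome_ids = c("nausea_intraop", "vomiting_intraop"))
  expect_s3_class(rb, "mvma_fit")
})

test_that("preset grid covers the declared scenario space and builds valid truths", {
  grid <- sim_preset_grid()
  expect_equal(nrow(grid), 4L * 3L * 3L * 3L)
  expect_setequal(unique(grid$k), c(5L, 10L, 20L, 50L))
  tr <- sim_preset("k10_tau0.3_rho0.5_mcar", seed = 3L)
  expect_s3_class(tr, "sim_truth")
  res <- generate_dataset(tr)
  expect_s3_class(res$dataset, "meta_dataset")
})
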