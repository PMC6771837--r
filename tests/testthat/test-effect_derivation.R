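test_that("log odds ratio follows the zero-cell rules", {
  # symmetric table: zero log OR, variance twice (1/10 + 1/90)
  e <- log_odds_ratio(list(events_t = 10, n_t = 100, events_c = 10, n_c = 100))
  expect_equal(e$log_or, 0)
  expect_equal(e$var, 2 * (1 / 10 + 1 / 90))
  expect_false(e$correction_applied)

  # hand evaluation of the standard formulas
  e <- log_odds_ratio(list(events_t = 10, n_t = 100, events_c = 5, n_c = 100))
  expect_equal(e$log_or, log((10 / 90) / (5 / 95)), tolerance = 1e-12)
  expect_equal(e$var, 1 / 10 + 1 / 90 + 1 / 5 + 1 / 95, tolerance = 1e-12)

  # zero events in both arms: no information, outcome missing
  e <- log_odds_ratio(list(events_t = 0, n_t = 50, events_c = 0, n_c = 50))
  expect_true(e$missing)
  expect_true(is.na(e$log_or))

  # zero events in one arm only: 0.5 added to every cell
  e <- log_odds_ratio(list(events_t = 0, n_t = 50, events_c = 5, n_c = 50))
  expect_true(e$correction_applied)
  expect_equal(e$log_or, log((0.5 / 50.5) / (5.5 / 45.5)), tolerance = 1e-12)
  expect_equal(e$var, 1 / 0.5 + 1 / 50.5 + 1 / 5.5 + 1 / 45.5, tolerance = 1e-12)
  expect_equal(e$log_or, -2.502, tolerance = 1e-3)
  expect_equal(e$var, 2.224, tolerance = 1e-3)

  # 100% events in one arm triggers the same correction
  e <- log_odds_ratio(list(events_t = 50, n_t = 50, events_c = 40, n_c = 50))
  expect_true(e$correction_applied)
})

test_that("exclusive-outcome correlation matches its hand-derived value and is negative", {
  a <- list(events_t = 30, n_t = 100, events_c = 25, n_c = 100)
  b <- list(events_t = 20, n_t = 100, events_c = 25, n_c = 100)
  r <- corr_mutually_exclusive(a, b)
  expect_equal(r$rho_w, -0.330, tolerance = 1e-2)
  # delta-method value computed from the per-arm multinomial covariance
  cov_expect <- -100 / (70 * 80) - 100 / (75 * 75)
  expect_equal(r$cov, cov_expect, tolerance = 1e-12)
  # symmetry under outcome swap
  r2 <- corr_mutually_exclusive(b, a)
  expect_equal(r2$rho_w, r$rho_w, tolerance = 1e-12)
  # sign invariant over a sweep of valid configurations
  set.seed(11)
  for (i in 1:25) {
    n <- sample(50:300, 1L)
    ea <- sample.int(floor(n / 3), 1L); eb <- sample.int(floor(n / 3), 1L)
    ca <- sample.int(floor(n / 3), 1L); cb <- sample.int(floor(n / 3), 1L)
    ta <- list(events_t = ea, n_t = n, events_c = ca, n_c = n)
    tb <- list(events_t = eb, n_t = n, events_c = cb, n_c = n)
    expect_lte(corr_mutually_exclusive(ta, tb)$rho_w, 0)
  }
  expect_error(
    corr_mutually_exclusive(a, list(events_t = 20, n_t = 90, events_c = 25,
                                    n_c = 100)),
    "arm totals differ")
})

test_that("subset-outcome correlation matches its hand-derived value, is positive, and hits 1 for identical counts", {
  sup <- list(events_t = 30, n_t = 100, events_c = 25, n_c = 100)
  sub <- list(events_t = 10, n_t = 100, events_c = 8, n_c = 100)
  r <- corr_subset(sub, sup)
  expect_equal(r$rho_w, 0.510, tolerance = 1e-2)
  cov_expect <- 100 / (30 * 90) + 100 / (25 * 92)
  expect_equal(r$cov, cov_expect, tolerance = 1e-12)

  # identical event counts in both arms: exactly 1 to machine precision
  eq <- list(events_t = 7, n_t = 120, events_c = 9, n_c = 118)
  expect_equal(corr_subset(eq, eq)$rho_w, 1, tolerance = 1e-14)
  # still exactly 1 when a zero cell forces the continuity correction
  eqz <- list(events_t = 0, n_t = 60, events_c = 4, n_c = 60)
  expect_equal(corr_subset(eqz, eqz)$rho_w, 1, tolerance = 1e-14)

  set.seed(12)
  for (i in 1:25) {
    n <- sample(50:300, 1L)
    st <- sample.int(floor(n / 2), 1L); ssub_t <- sample.int(st, 1L)
    sc <- sample.int(floor(n / 2), 1L); ssub_c <- sample.int(sc, 1L)
    tsup <- list(events_t = st, n_t = n, events_c = sc, n_c = n)
    tsub <- list(events_t = ssub_t, n_t = n, events_c = ssub_c, n_c = n)
    expect_gte(corr_subset(tsub, tsup)$rho_w, 0)
  }
  expect_error(corr_subset(sup, sub), "more events than its superset")
})

test_that("delta-method correlations agree with small Monte-Carlo oracles", {
  set.seed(202)
  r_mc <- mc_corr_exclusive(30, 20, 100, 25, 25, 100, reps = 4e4)
  a <- list(events_t = 30, n_t = 100, events_c = 25, n_c = 100)
  b <- list(events_t = 20, n_t = 100, events_c = 25, n_c = 100)
  expect_lt(abs(corr_mutually_exclusive(a, b)$rho_w - r_mc), 0.03)

  r_mc <- mc_corr_subset(10, 30, 100, 8, 25, 100, reps = 4e4)
  sup <- list(events_t = 30, n_t = 100, events_c = 25, n_c = 100)
  sub <- list(events_t = 10, n_t = 100, events_c = 8, n_c = 100)
  expect_lt(abs(corr_subset(sub, sup)$rho_w - r_mc), 0.03)
})

test_that("within-study covariance assembly routes analytic, fixed and unavailable entries", {
  ds <- fixture_exclusive()
  wc <- assemble_within_cov(ds)
  expect_length(wc, 4L)
  expect_true(attr(wc, "complete"))
  eff <- derive_effects(ds)
  for (s in names(wc)) {
    S <- wc[[s]]$matrix
    expect_equal(dim(S), c(2L, 2L))
    es <- eff[eff$study_id == s, ]
    expect_equal(unname(diag(S)), es$var[match(wc[[s]]$outcome_ids,
                                               es$outcome_id)])
    expect_lt(S[1L, 2L], 0)
    expect_equal(S[1L, 2L], S[2L, 1L])
    rho <- S[1L, 2L] / sqrt(S[1L, 1L] * S[2L, 2L])
    expect_true(rho >= -1 && rho <= 1)
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(unname(wc[[s]]$source[1L, 2L]), "analytic_exclusive")
  }

  # unrelated pair without fixed correlations: flagged unavailable,
  # dataset routed away from the hierarchical model
  ds_un <- meta_dataset(fixture_exclusive()$tables)
  wc_un <- assemble_within_cov(ds_un)
  expect_false(attr(wc_un, "complete"))
  expect_equal(unname(wc_un$s1$source[1L, 2L]), "unavailable")
  expect_equal(unname(wc_un$s1$matrix[1L, 2L]), 0)

  # user-supplied fixed correlations fill the unrelated pair
  fc <- matrix(c(1, 0.6, 0.6, 1), 2L,
               dimnames = list(c("caesarean", "instrumental"),
                               c("caesarean", "instrumental")))
  wc_fx <- assemble_within_cov(ds_un, fixed_corr = fc)
  expect_true(attr(wc_fx, "complete"))
  expect_equal(unname(wc_fx$s1$source[1L, 2L]), "fixed_external")
  expect_equal(wc_fx$s1$matrix[1L, 2L],
               0.6 * sqrt(prod(diag(wc_fx$s1$matrix))), tolerance = 1e-12)
})

test_that("indefinite fixed-correlation assemblies are shrunk back to PSD with a warning", {
  tab <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(study_id = "s1", outcome_id = paste0("o", i),
               events_t = 20L + i, n_t = 100L, events_c = 18L, n_c = 100L,
               stringsAsFactors = FALSE)
  }))
  ds <- meta_dataset(tab)
  # rho(1,2) = rho(1,3) = 0.9 with rho(2,3) = -0.9 is not a valid
  # correlation structure
  fc <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3L,
               dimnames = list(paste0("o", 1:3), paste0("o", 1:3)))
  expect_warning(wc <- assemble_within_cov(ds, fixed_corr = fc),
                 "not positive semi-definite")
  ev <- eigen(wc$s1$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})
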