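#' Log odds ratio from a 2x2 table with zero-cell rules
#'
#' Applies the standard rules for sparse binary data: a study with zero
#' events in both arms carries no information about the odds ratio and the
#' outcome is treated as missing in that study; otherwise, if any of the
#' four cells (events or non-events in either arm) is zero, 0.5 is added to
#' all four cells before the log OR and its variance are computed.
#'
#' @param table one-row data.frame (or list) with `events_t`, `n_t`,
#'   `events_c`, `n_c`.
#' @return list with `log_or`, `var`, `correction_applied`, `missing`, and
#'   `cells` — the (possibly corrected) counts `a` (treatment events),
#'   `b` (treatment non-events), `c` (control events), `d` (control
#'   non-events) used in the computation (`NULL` when missing).
#' @export
log_odds_ratio <- function(table) {
  a <- as.numeric(table$events_t); n1 <- as.numeric(table$n_t)
  c_ <- as.numeric(table$events_c); n0 <- as.numeric(table$n_c)
  b <- n1 - a; d <- n0 - c_
  if (a == 0 && c_ == 0) {
    return(list(log_or = NA_real_, var = NA_real_,
                correction_applied = FALSE, missing = TRUE, cells = NULL))
  }
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  list(
    log_or = log((a / b) / (c_ / d)),
    var = 1 / a + 1 / b + 1 / c_ + 1 / d,
    correction_applied = corrected,
    missing = FALSE,
    cells = c(a = a, b = b, c = c_, d = d)
  )
}

#' Derive log odds ratios for every table in a dataset
#'
#' @param dataset a [meta_dataset].
#' @return data.frame with one row per (study, outcome) table: `study_id`,
#'   `outcome_id`, `log_or`, `var`, `correction_applied`, `missing`.
#' @export
derive_effects <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  tab <- dataset$tables
  res <- lapply(seq_len(nrow(tab)), function(i) log_odds_ratio(tab[i, ]))
  data.frame(
    study_id = tab$study_id,
    outcome_id = tab$outcome_id,
    log_or = vapply(res, `[[`, numeric(1L), "log_or"),
    var = vapply(res, `[[`, numeric(1L), "var"),
    correction_applied = vapply(res, `[[`, logical(1L), "correction_applied"),
    missing = vapply(res, `[[`, logical(1L), "missing"),
    stringsAsFactors = FALSE
  )
}

# Effective cells for correlation formulas: the same (possibly 0.5-corrected)
# counts that produced the log OR, so that the diagonal and off-diagonal of
# the assembled within-study covariance matrix are mutually consistent.
effective_cells <- function(table) {
  eff <- log_odds_ratio(table)
  if (eff$missing) {
    stop("cannot derive a correlation involving a double-zero (missing) outcome")
  }
  eff
}

#' Within-study correlation for two mutually exclusive outcomes
#'
#' Delta-method correlation between the log odds ratios of two mutually
#' exclusive binary outcomes measured on the same patients. Per arm, the
#' counts of the two events and of patients with neither follow a
#' multinomial distribution, which induces covariance
#' \eqn{-n / ((n - a)(n - b))} between the two log odds; the study-level
#' covariance of the log ORs sums the two arms, and the correlation divides
#' by the product of the standard errors. It is never positive: one event
#' occurring precludes the other.
#'
#' When a table triggered the 0.5 continuity correction the corrected cells
#' are used, keeping the correlation consistent with that table's variance.
#'
#' @param table_a,table_b one-row 2x2 tables for the two outcomes in the
#'   same study (arm totals must agree).
#' @return list with `rho_w` (the correlation), `cov` (covariance of the
#'   two log ORs), `var_a`, `var_b`.
#' @export
corr_mutually_exclusive <- function(table_a, table_b) {
  check_same_arms(table_a, table_b)
  ea <- effective_cells(table_a)
  eb <- effective_cells(table_b)
  # per arm: cov(logit_a, logit_b) = -n / ((n - a)(n - b)); with corrected
  # cells the effective total is a + b per table, combined geometrically so
  # equal corrections reduce to the plain corrected-count formula
  cov_t <- -arm_total(ea, eb, "t") / (ea$cells[["b"]] * eb$cells[["b"]])
  cov_c <- -arm_total(ea, eb, "c") / (ea$cells[["d"]] * eb$cells[["d"]])
  cov <- cov_t + cov_c
  rho <- cov / sqrt(ea$var * eb$var)
  list(rho_w = rho, cov = cov, var_a = ea$var, var_b = eb$var)
}

#' Within-study correlation for a subset outcome and its superset
#'
#' Delta-method correlation between the log odds ratios of two nested
#' binary outcomes (every event of the subset outcome is also an event of
#' the superset, e.g. caesarean section within operative birth). Per arm
#' the covariance of the two log odds is \eqn{n / (a_{sup} (n - a_{sub}))};
#' arms are summed and standardised as in [corr_mutually_exclusive()]. The
#' correlation is never negative, and equals exactly 1 when the two
#' outcomes have identical event counts in both arms (the outcomes are then
#' observationally indistinguishable).
#'
#' @param table_subset one-row 2x2 table of the subset outcome.
#' @param table_superset one-row 2x2 table of the superset outcome.
#' @return list with `rho_w`, `cov`, `var_sub`, `var_sup`.
#' @export
corr_subset <- function(table_subset, table_superset) {
  check_same_arms(table_subset, table_superset)
  if (table_subset$events_t > table_superset$events_t ||
      table_subset$events_c > table_superset$events_c) {
    stop("subset outcome has more events than its superset")
  }
  es <- effective_cells(table_subset)
  ep <- effective_cells(table_superset)
  # per arm: cov(logit_sub, logit_sup) = n / (a_sup (n - a_sub))
  cov_t <- arm_total(es, ep, "t") / (ep$cells[["a"]] * es$cells[["b"]])
  cov_c <- arm_total(es, ep, "c") / (ep$cells[["c"]] * es$cells[["d"]])
  cov <- cov_t + cov_c
  rho <- cov / sqrt(es$var * ep$var)
  list(rho_w = rho, cov = cov, var_sub = es$var, var_sup = ep$var)
}

check_same_arms <- function(x, y) {
  if (x$n_t != y$n_t || x$n_c != y$n_c) {
    stop("arm totals differ between the two outcomes' tables")
  }
  invisible(TRUE)
}

# Effective per-arm total: geometric mean of the two tables' effective
# totals (raw n, or n + 1 where a table was 0.5-corrected), so the exact
# rho = 1 identity for identical subset/superset counts survives correction.
arm_total <- function(ea, eb, arm) {
  if (arm == "t") {
    na <- ea$cells[["a"]] + ea$cells[["b"]]
    nb <- eb$cells[["a"]] + eb$cells[["b"]]
  } else {
    na <- ea$cells[["c"]] + ea$cells[["d"]]
    nb <- eb$cells[["c"]] + eb$cells[["d"]]
  }
  sqrt(na * nb)
}

#' Within-study correlations for all structurally related pairs
#'
#' @param dataset a [meta_dataset].
#' @return data.frame with columns `study_id`, `outcome_a`, `outcome_b`,
#'   `rho_w`, `source` (`analytic_exclusive` or `analytic_subset`), one row
#'   per study per related pair where both outcomes are reported and
#'   non-missing.
#' @export
derive_correlations <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  rel <- dataset$relations
  out <- list()
  tab <- dataset$tables
  for (i in seq_len(nrow(rel))) {
    r <- rel$relation[i]
    if (r == "unrelated") next
    a <- rel$outcome_a[i]; b <- rel$outcome_b[i]
    ta <- tab[tab$outcome_id == a, , drop = FALSE]
    tb <- tab[tab$outcome_id == b, , drop = FALSE]
    for (s in intersect(ta$study_id, tb$study_id)) {
      xa <- ta[ta$study_id == s, ]
      xb <- tb[tb$study_id == s, ]
      if ((xa$events_t == 0 && xa$events_c == 0) ||
          (xb$events_t == 0 && xb$events_c == 0)) next
      if (r == "mutually_exclusive") {
        rho <- corr_mutually_exclusive(xa, xb)$rho_w
        src <- "analytic_exclusive"
      } else if (r == "subset_a_of_b") {
        rho <- corr_subset(xa, xb)$rho_w
        src <- "analytic_subset"
      } else {
        rho <- corr_subset(xb, xa)$rho_w
        src <- "analytic_subset"
      }
      out[[length(out) + 1L]] <- data.frame(
        study_id = s, outcome_a = a, outcome_b = b, rho_w = rho,
        source = src, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(study_id = character(), outcome_a = character(),
                      outcome_b = character(), rho_w = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assemble per-study within-study covariance matrices
#'
#' Builds, for every study, the covariance matrix S of its non-missing log
#' odds ratios: variances on the diagonal; off-diagonals from the analytic
#' correlations for structurally related pairs, from a user-supplied fixed
#' correlation matrix for the remaining pairs if given, and otherwise
#' flagged unavailable (entry left at 0, source `"unavailable"`). The
#' attribute `"complete"` on the returned list reports whether every
#' off-diagonal of every matrix was available — this drives the choice
#' between the fully hierarchical multivariate model (needs complete S) and
#' the Riley overall-correlation model (does not).
#'
#' Correlations are clamped to ±0.999999 before assembly so S is never
#' exactly singular. If a user-supplied fixed correlation matrix makes an
#' assembled S indefinite (possible with 3+ outcomes), the unavailable and
#' fixed off-diagonals are shrunk toward zero by the smallest uniform
#' factor restoring positive semi-definiteness (eigenvalue floor 1e-8) and
#' a warning is issued.
#'
#' @param dataset a [meta_dataset].
#' @param fixed_corr optional symmetric matrix of correlations with
#'   dimnames equal to outcome ids, used for pairs without a structural
#'   relation.
#' @return named list (by study id) of objects with fields `study_id`,
#'   `outcome_ids`, `matrix`, `source` (character matrix); attribute
#'   `"complete"`.
#' @export
assemble_within_cov <- function(dataset, fixed_corr = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  effects <- derive_effects(dataset)
  effects <- effects[!effects$missing, , drop = FALSE]
  corrs <- derive_correlations(dataset)
  studies <- unique(effects$study_id)
  complete <- TRUE
  out <- list()
  for (s in studies) {
    eff_s <- effects[effects$study_id == s, , drop = FALSE]
    oids <- intersect(dataset$outcome_ids, eff_s$outcome_id)
    d <- length(oids)
    S <- diag(eff_s$var[match(oids, eff_s$outcome_id)], nrow = d)
    dimnames(S) <- list(oids, oids)
    src <- matrix("", d, d, dimnames = list(oids, oids))
    diag(src) <- "variance"
    if (d >= 2L) {
      for (j in seq_len(d - 1L)) {
        for (k in (j + 1L):d) {
          a <- oids[j]; b <- oids[k]
          hit <- corrs[corrs$study_id == s &
                         ((corrs$outcome_a == a & corrs$outcome_b == b) |
                            (corrs$outcome_a == b & corrs$outcome_b == a)), ,
                       drop = FALSE]
          if (nrow(hit) == 1L) {
            rho <- clamp_corr(hit$rho_w)
            src[j, k] <- src[k, j] <- hit$source
          } else if (!is.null(fixed_corr) &&
                     a %in% rownames(fixed_corr) && b %in% colnames(fixed_corr)) {
            rho <- clamp_corr(fixed_corr[a, b])
            src[j, k] <- src[k, j] <- "fixed_external"
          } else {
            rho <- 0
            src[j, k] <- src[k, j] <- "unavailable"
            complete <- FALSE
          }
          S[j, k] <- S[k, j] <- rho * sqrt(S[j, j] * S[k, k])
        }
      }
      S <- ensure_psd(S, src, s)
    }
    out[[s]] <- list(study_id = s, outcome_ids = oids, matrix = S, source = src)
  }
  attr(out, "complete") <- complete
  out
}

clamp_corr <- function(rho, limit = 0.999999) {
  max(min(rho, limit), -limit)
}

# Uniform off-diagonal shrinkage to restore positive semi-definiteness;
# only reachable with user-supplied fixed correlations on 3+ outcomes.
ensure_psd <- function(S, src, study_id, floor = 1e-8) {
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >= floor * max(diag(S))) {
    return(S)
  }
  f_lo <- 0; f_hi <- 1
  off <- S; diag(off) <- 0
  D <- diag(diag(S), nrow = nrow(S))
  for (iter in 1:60) {
    f <- (f_lo + f_hi) / 2
    cand <- D + f * off
    if (min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values) >=
        floor * max(diag(S))) f_lo <- f else f_hi <- f
  }
  warning(sprintf(
    "study '%s': assembled within-study covariance was not positive semi-definite; off-diagonals shrunk by factor %.4f",
    study_id, f_lo))
  D + f_lo * off
}

#' Export derived effects and correlations as CSV
#'
#' @param dataset a [meta_dataset].
#' @param effects_path output CSV for per-table effects.
#' @param correlations_path optional output CSV for per-study within-study
#'   correlations of related pairs.
#' @return invisibly, the effects data.frame.
#' @export
export_effects <- function(dataset, effects_path, correlations_path = NULL) {
  eff <- derive_effects(dataset)
  write.csv(eff, effects_path, row.names = FALSE)
  if (!is.null(correlations_path)) {
    write.csv(derive_correlations(dataset), correlations_path, row.names = FALSE)
  }
  invisible(eff)
}
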