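# Restricted log-likelihood of the random-effects model
# y_i ~ N(mu, v_i + tau2), with mu profiled out by GLS. Returned value
# omits the -(k-1)/2 log(2*pi) constant.
uvma_restricted_ll <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

# Joint (unprofiled) restricted objective in (mu, tau2); the observed
# information of this surface at the optimum yields a standard error for mu
# that accounts for the uncertainty in tau2.
uvma_joint_ll <- function(mu, tau2, y, v) {
  w <- 1 / (v + tau2)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' Univariate random-effects meta-analysis by REML
#'
#' Fits \eqn{y_i \sim N(\mu, s_i^2 + \tau^2)} to the non-missing log odds
#' ratios of one outcome. The between-study variance \eqn{\tau^2} maximises
#' the restricted log-likelihood (profiled over \eqn{\mu}), searched on the
#' log-variance scale with an explicit comparison against the \eqn{\tau^2 =
#' 0} boundary; \eqn{\mu} is the inverse-variance-weighted mean at the
#' fitted \eqn{\tau^2}.
#'
#' By default the standard error of \eqn{\mu} comes from the observed
#' information of the joint restricted objective in \eqn{(\mu, \tau^2)},
#' so it reflects the uncertainty in the between-study variance estimate;
#' `se_method = "gls"` gives the plain \eqn{1/\sqrt{\sum w_i}} standard
#' error instead. 95% confidence intervals use the normal quantile.
#'
#' @param effects data.frame as returned by [derive_effects()], restricted
#'   to (or filtered internally for) a single outcome; rows with
#'   `missing = TRUE` are dropped.
#' @param outcome_id optional outcome to select when `effects` spans
#'   several.
#' @param fixed_tau2 optional non-negative value at which to hold
#'   \eqn{\tau^2} fixed (0 gives the common-effect inverse-variance
#'   estimate).
#' @param se_method `"information"` (default) or `"gls"`.
#' @return An object of class `uvma_fit`: `outcome_id`, `mu`, `se_mu`,
#'   `tau`, `ci_low`, `ci_high`, `n_studies`, `status`, `loglik`.
#' @export
fit_uvma <- function(effects, outcome_id = NULL, fixed_tau2 = NULL,
                     se_method = c("information", "gls")) {
  se_method <- match.arg(se_method)
  if (!is.null(outcome_id)) {
    effects <- effects[effects$outcome_id == outcome_id, , drop = FALSE]
  }
  effects <- effects[!effects$missing, , drop = FALSE]
  if (nrow(effects) < 2L) {
    stop("univariate fit needs at least 2 non-missing effects")
  }
  oid <- unique(effects$outcome_id)
  if (length(oid) != 1L) {
    stop("effects span multiple outcomes; pass 'outcome_id'")
  }
  y <- effects$log_or
  v <- effects$var
  k <- length(y)

  if (is.null(fixed_tau2)) {
    upper <- max(10, 10 * stats::var(y))
    opt <- optimize(function(z) uvma_restricted_ll(exp(z), y, v),
                    interval = c(log(1e-12), log(upper)),
                    maximum = TRUE, tol = 1e-10)
    tau2 <- exp(opt$maximum)
    ll <- opt$objective
    ll0 <- uvma_restricted_ll(0, y, v)
    if (ll0 >= ll - 1e-10) { # boundary check at tau2 = 0
      tau2 <- 0
      ll <- ll0
    }
  } else {
    stopifnot(fixed_tau2 >= 0)
    tau2 <- fixed_tau2
    ll <- uvma_restricted_ll(tau2, y, v)
  }

  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se_gls <- 1 / sqrt(sum(w))
  se <- se_gls
  if (se_method == "information" && is.null(fixed_tau2) && tau2 > 1e-8) {
    H <- pracma::hessian(function(p) -uvma_joint_ll(p[1], p[2], y, v),
                         c(mu, tau2))
    se_info <- tryCatch({
      V <- solve(H)
      if (V[1, 1] > 0) sqrt(V[1, 1]) else NA_real_
    }, error = function(e) NA_real_)
    if (is.finite(se_info)) se <- se_info
  }

  structure(list(
    outcome_id = oid,
    mu = mu,
    se_mu = se,
    se_gls = se_gls,
    tau = sqrt(tau2),
    ci_low = mu - qnorm(0.975) * se,
    ci_high = mu + qnorm(0.975) * se,
    n_studies = k,
    status = "converged",
    loglik = ll
  ), class = "uvma_fit")
}

#' @export
print.uvma_fit <- function(x, ...) {
  cat(sprintf("Univariate random-effects meta-analysis (REML), outcome '%s'\n",
              x$outcome_id))
  cat(sprintf("  k = %d studies\n", x$n_studies))
  cat(sprintf("  summary OR %.3f (95%% CI %.3f-%.3f)\n",
              exp(x$mu), exp(x$ci_low), exp(x$ci_high)))
  cat(sprintf("  log OR %.4f (SE %.4f), between-study SD tau = %.4f\n",
              x$mu, x$se_mu, x$tau))
  invisible(x)
}

#' Fit univariate meta-analyses for all eligible outcomes of a dataset
#'
#' @param dataset a [meta_dataset].
#' @param min_studies eligibility threshold passed to
#'   [eligibility_filter()].
#' @param ... further arguments to [fit_uvma()].
#' @return named list of `uvma_fit` objects, one per eligible outcome.
#' @export
fit_uvma_all <- function(dataset, min_studies = 3L, ...) {
  rep <- eligibility_filter(dataset, min_studies)
  effects <- derive_effects(dataset)
  oids <- rep$outcome_id[rep$eligible]
  setNames(lapply(oids, function(oid) fit_uvma(effects, outcome_id = oid, ...)),
           oids)
}
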