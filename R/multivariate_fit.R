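#' Fitting options for multivariate meta-analysis
#'
#' @param restricted logical; `TRUE` (default) for REML, `FALSE` for ML.
#' @param max_iterations optimizer iteration cap per start.
#' @param objective_tolerance convergence tolerance on the objective.
#' @param n_random_starts maximum number of optimizer starts (the first is
#'   deterministic; later starts are seeded random perturbations).
#' @param seed integer seed driving the random restarts.
#' @param fix_correlations optional symmetric matrix (dimnames = outcome
#'   ids) of correlations to hold fixed: between-study correlations for the
#'   hierarchical model, overall correlations for the Riley model. `NA`
#'   entries remain free.
#' @param fix_tau optional named vector of between-study SDs to hold
#'   fixed; with a complete `fix_correlations` all variance parameters are
#'   fixed and only the summary effects are estimated by generalized least
#'   squares, while on its own the correlations remain free (used for
#'   profile-likelihood checks over the correlation alone).
#' @return list of class `fit_options`.
#' @export
fit_options <- function(restricted = TRUE, max_iterations = 500L,
                        objective_tolerance = 1e-8, n_random_starts = 10L,
                        seed = 1L, fix_correlations = NULL, fix_tau = NULL) {
  stopifnot(n_random_starts >= 1L, objective_tolerance > 0)
  structure(list(restricted = restricted, max_iterations = max_iterations,
                 objective_tolerance = objective_tolerance,
                 n_random_starts = as.integer(n_random_starts),
                 seed = as.integer(seed),
                 fix_correlations = fix_correlations, fix_tau = fix_tau),
            class = "fit_options")
}

BOUNDARY_EPS <- 1e-4      # |rho| beyond 1 - 1e-4 is reported at the boundary
Z_MAX <- atanh(1 - 1e-6)  # Fisher-z box constraint for correlations
LOG_SD_MIN <- -8          # log between-study SD lower bound (sd ~ 3e-4)
LOG_SD_MAX <- 3

# Per-study fitting data: observed outcome indices, effect vector, within
# covariance matrix (diagonal when correlations are not used).
build_study_data <- function(effects, outcome_ids, within_cov = NULL) {
  effects <- effects[!effects$missing, , drop = FALSE]
  effects <- effects[effects$outcome_id %in% outcome_ids, , drop = FALSE]
  studies <- unique(effects$study_id)
  out <- lapply(studies, function(s) {
    eff_s <- effects[effects$study_id == s, , drop = FALSE]
    oids <- intersect(outcome_ids, eff_s$outcome_id)
    idx <- match(oids, outcome_ids)
    y <- eff_s$log_or[match(oids, eff_s$outcome_id)]
    if (!is.null(within_cov) && s %in% names(within_cov)) {
      S_full <- within_cov[[s]]$matrix
      S <- S_full[oids, oids, drop = FALSE]
      src <- within_cov[[s]]$source[oids, oids, drop = FALSE]
    } else {
      S <- diag(eff_s$var[match(oids, eff_s$outcome_id)], nrow = length(oids))
      dimnames(S) <- list(oids, oids)
      src <- NULL
    }
    list(study_id = s, idx = idx, y = y, S = S, source = src)
  })
  names(out) <- studies
  out
}

# Negative (restricted) log-likelihood with the summary effects profiled
# out by GLS. Vfun(theta, study) returns the marginal covariance of the
# study's observed effect vector. Returns Inf-like penalty on failure.
mvma_negll <- function(theta, studies, d, Vfun, restricted, details = FALSE) {
  A <- matrix(0, d, d)
  b <- numeric(d)
  quad <- 0
  logdet <- 0
  for (st in studies) {
    V <- Vfun(theta, st)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(if (details) NULL else 1e10)
    Vinv <- chol2inv(ch)
    A[st$idx, st$idx] <- A[st$idx, st$idx] + Vinv
    b[st$idx] <- b[st$idx] + Vinv %*% st$y
    quad <- quad + sum(st$y * (Vinv %*% st$y))
    logdet <- logdet + 2 * sum(log(diag(ch)))
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(if (details) NULL else 1e10)
  mu <- chol2inv(chA) %*% b
  val <- 0.5 * (logdet + quad - sum(b * mu))
  if (restricted) val <- val + 0.5 * 2 * sum(log(diag(chA)))
  if (!is.finite(val)) return(if (details) NULL else 1e10)
  if (details) {
    list(negll = val, mu = drop(mu), A = A, cov_mu_gls = chol2inv(chA))
  } else {
    val
  }
}

# Joint (unprofiled) negative restricted objective in (mu, theta); its
# observed information at the optimum gives a covariance for mu that
# carries the uncertainty of the variance parameters.
mvma_joint_negll <- function(mu, theta, studies, d, Vfun, restricted) {
  quad <- 0
  logdet <- 0
  A <- matrix(0, d, d)
  for (st in studies) {
    V <- Vfun(theta, st)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vinv <- chol2inv(ch)
    r <- st$y - mu[st$idx]
    quad <- quad + sum(r * (Vinv %*% r))
    logdet <- logdet + 2 * sum(log(diag(ch)))
    if (restricted) A[st$idx, st$idx] <- A[st$idx, st$idx] + Vinv
  }
  val <- 0.5 * (logdet + quad)
  if (restricted) {
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(1e10)
    val <- val + sum(log(diag(chA)))
  }
  if (!is.finite(val)) 1e10 else val
}

#' Convergence policy for a completed optimizer run
#'
#' Declares a run converged when (i) the optimizer reported a successful
#' stop under the objective tolerance, (ii) the gradient of the objective
#' on the unconstrained parameter scale is numerically zero (norm below
#' `1e-5`, relative to the objective magnitude) except in directions
#' pinned at a box boundary (correlations at ±1, variance floor), and
#' (iii) the Hessian over the non-boundary parameters is positive
#' semi-definite to tolerance `1e-6` (the objective is a negative
#' log-likelihood, so this is curvature consistent with a maximum of the
#' likelihood). Where ill-conditioning makes the raw gradient norm
#' unattainable, the Newton decrement \eqn{g^T H^{-1} g / 2} — the
#' attainable objective improvement — may satisfy the gradient condition
#' instead (relative tolerance `1e-6`). Non-convergence is a reportable
#' state, not an error.
#'
#' @param trace list with `par`, `value`, `convergence` (optim code),
#'   `objective` (the objective function), `lower`, `upper`.
#' @param options a [fit_options] object.
#' @return list with `status` (`"converged"` or `"failed_convergence"`)
#'   and `diagnostics` (gradient norm, minimum Hessian eigenvalue,
#'   boundary mask, message).
#' @export
convergence_policy <- function(trace, options) {
  p <- length(trace$par)
  diagnostics <- list(grad_norm = NA_real_, min_hessian_eig = NA_real_,
                      at_boundary = logical(p), message = "")
  # stop code 1 means the iteration cap was hit (improvement criterion not
  # met); codes 51/52 are line-search terminations at points where no
  # further improvement was found — for those the gradient and curvature
  # checks below adjudicate
  if (!is.null(trace$convergence) && !trace$convergence %in% c(0L, 51L, 52L)) {
    diagnostics$message <- sprintf("optimizer stop code %d", trace$convergence)
    return(list(status = "failed_convergence", diagnostics = diagnostics))
  }
  if (p == 0L) {
    diagnostics$message <- "no free variance parameters (GLS)"
    return(list(status = "converged", diagnostics = diagnostics))
  }
  at_bound <- (trace$par - trace$lower < 1e-6) | (trace$upper - trace$par < 1e-6)
  diagnostics$at_boundary <- at_bound
  g <- tryCatch(pracma::grad(trace$objective, trace$par),
                error = function(e) rep(NA_real_, p))
  free <- !at_bound
  gn <- if (any(free)) sqrt(sum(g[free]^2)) else 0
  diagnostics$grad_norm <- gn
  tol_g <- 1e-5 * max(1, abs(trace$value))
  if (!is.finite(gn)) {
    diagnostics$message <- "gradient evaluation failed"
    return(list(status = "failed_convergence", diagnostics = diagnostics))
  }
  if (any(free)) {
    H <- tryCatch(pracma::hessian(trace$objective, trace$par),
                  error = function(e) NULL)
    if (is.null(H)) {
      diagnostics$message <- "Hessian evaluation failed"
      return(list(status = "failed_convergence", diagnostics = diagnostics))
    }
    Hf <- H[free, free, drop = FALSE]
    Hf <- (Hf + t(Hf)) / 2
    ev <- eigen(Hf, symmetric = TRUE, only.values = TRUE)$values
    diagnostics$min_hessian_eig <- min(ev)
    if (min(ev) < -1e-6 * max(1, max(abs(ev)))) {
      diagnostics$message <- "objective not locally convex at the solution"
      return(list(status = "failed_convergence", diagnostics = diagnostics))
    }
    if (gn > tol_g) {
      # in ill-conditioned regions the raw gradient norm overstates how
      # far the solution is from the optimum; the Newton decrement
      # g'H^{-1}g/2 estimates the attainable objective improvement
      decrement <- tryCatch(0.5 * sum(g[free] * solve(Hf, g[free])),
                            error = function(e) NA_real_)
      diagnostics$newton_decrement <- decrement
      if (!is.finite(decrement) || decrement < 0 ||
          decrement > 1e-6 * max(1, abs(trace$value))) {
        diagnostics$message <- "gradient not numerically zero away from boundaries"
        return(list(status = "failed_convergence", diagnostics = diagnostics))
      }
    }
  } else if (gn > tol_g) {
    diagnostics$message <- "gradient not numerically zero away from boundaries"
    return(list(status = "failed_convergence", diagnostics = diagnostics))
  }
  diagnostics$message <- "converged"
  list(status = "converged", diagnostics = diagnostics)
}

# Shared estimation engine: multi-start bounded quasi-Newton optimization
# of the profiled (restricted) likelihood, convergence policy, and
# information-based covariance of the summary effects.
fit_mvma_engine <- function(studies, outcome_ids, Vfun, par_spec, options,
                            model_label) {
  d <- length(outcome_ids)
  restricted <- options$restricted
  obj <- function(theta) mvma_negll(theta, studies, d, Vfun, restricted)
  p <- length(par_spec$init)

  n_joint <- sum(vapply(studies, function(st) length(st$idx) >= 2L, logical(1L)))
  if (p > 0L && par_spec$has_free_corr && n_joint == 0L) {
    return(mvma_failure(outcome_ids, model_label, options,
                        "no study reports two outcomes jointly; correlation parameters are not identifiable",
                        n_starts = 0L))
  }

  # which parameter directions are pinned: at a box bound, or a Fisher-z
  # correlation whose implied rho has reached the reporting boundary
  pinned_mask <- function(par) {
    m <- (par - par_spec$lower < 1e-6) | (par_spec$upper - par < 1e-6)
    ci <- par_spec$corr_idx
    if (!is.null(ci)) m[ci] <- m[ci] | abs(tanh(par[ci])) > 1 - BOUNDARY_EPS
    m
  }
  factr <- max(10, options$objective_tolerance / .Machine$double.eps)
  polish_and_assess <- function(run) {
    mask <- pinned_mask(run$par)
    if (any(mask) && !all(mask)) {
      # hold boundary directions at the boundary and re-optimize the rest
      pin <- run$par
      ci <- par_spec$corr_idx
      if (!is.null(ci)) pin[ci][mask[ci]] <- sign(pin[ci][mask[ci]]) * Z_MAX
      free <- which(!mask)
      robj <- function(thf) { th <- pin; th[free] <- thf; obj(th) }
      pol_run <- tryCatch(
        optim(run$par[free], robj, method = "L-BFGS-B",
              lower = par_spec$lower[free], upper = par_spec$upper[free],
              control = list(maxit = options$max_iterations, factr = factr,
                             pgtol = 1e-8, ndeps = rep(1e-6, length(free)))),
        error = function(e) NULL)
      if (!is.null(pol_run) && is.finite(pol_run$value) &&
          pol_run$value <= run$value + 1e-10) {
        par2 <- pin
        par2[free] <- pol_run$par
        run <- list(par = par2, value = pol_run$value,
                    convergence = pol_run$convergence)
        mask <- pinned_mask(run$par)
      }
    }
    free <- which(!mask)
    policy <- if (length(free) == 0L) {
      list(status = "converged",
           diagnostics = list(grad_norm = 0, min_hessian_eig = NA_real_,
                              at_boundary = mask,
                              message = "all parameters on a boundary"))
    } else {
      pin <- run$par
      robj <- function(thf) { th <- pin; th[free] <- thf; obj(th) }
      pol <- convergence_policy(
        list(par = run$par[free], value = run$value,
             convergence = run$convergence, objective = robj,
             lower = par_spec$lower[free], upper = par_spec$upper[free]),
        options)
      pol$diagnostics$at_boundary <- mask
      pol
    }
    list(run = run, policy = policy)
  }

  best <- NULL
  starts_used <- 0L
  policy <- NULL
  if (p == 0L) {
    starts_used <- 1L
    best <- list(par = numeric(0), value = obj(numeric(0)), convergence = 0L)
    policy <- list(status = "converged",
                   diagnostics = list(message = "no free variance parameters (GLS)"))
  } else {
    for (attempt in seq_len(options$n_random_starts)) {
      starts_used <- attempt
      # start 1: deterministic init; start 2: warm restart from the best
      # solution so far (resets the quasi-Newton state, which helps in
      # ill-conditioned boundary regions); later starts: seeded jitter
      if (attempt == 1L || (attempt > 2L && is.null(best))) {
        theta0 <- par_spec$init
      } else {
        theta0 <- best$par
      }
      if (attempt > 2L) {
        set.seed(options$seed * 1000L + attempt)
        theta0 <- theta0 + rnorm(p, sd = 0.25 * (attempt - 2L))
      }
      theta0 <- pmin(pmax(theta0, par_spec$lower + 1e-3),
                     par_spec$upper - 1e-3)
      run <- tryCatch(
        optim(theta0, obj, method = "L-BFGS-B",
              lower = par_spec$lower, upper = par_spec$upper,
              control = list(maxit = options$max_iterations,
                             factr = factr, pgtol = 1e-8,
                             ndeps = rep(1e-6, p))),
        error = function(e) NULL)
      if (is.null(run) || !is.finite(run$value) || run$value >= 1e9) next
      if (is.null(best) || run$value < best$value - 1e-10) {
        assessed <- polish_and_assess(run)
        if (is.null(best) || assessed$run$value < best$value - 1e-10) {
          best <- assessed$run
          policy <- assessed$policy
        }
      }
      if (!is.null(policy) && policy$status == "converged") break
    }
    if (is.null(best)) {
      return(mvma_failure(outcome_ids, model_label, options,
                          "all optimizer starts failed", starts_used))
    }
    if (is.null(policy)) {
      policy <- list(status = "failed_convergence",
                     diagnostics = list(message = "no successful start"))
    }
  }

  det <- mvma_negll(best$par, studies, d, Vfun, restricted, details = TRUE)
  if (is.null(det)) {
    return(mvma_failure(outcome_ids, model_label, options,
                        "likelihood not evaluable at the solution", starts_used))
  }
  est <- par_spec$extract(best$par)

  # covariance of mu from the observed information of the joint objective,
  # holding boundary-pinned variance parameters fixed; GLS fallback
  cov_mu <- det$cov_mu_gls
  cov_src <- "gls"
  free <- if (p > 0L) {
    !pinned_mask(best$par) &
      !((best$par - par_spec$lower < 1e-3) | (par_spec$upper - best$par < 1e-3))
  } else logical(0)
  if (any(free)) {
    full <- function(q) {
      th <- best$par
      th[free] <- q[-seq_len(d)]
      mvma_joint_negll(q[seq_len(d)], th, studies, d, Vfun, restricted)
    }
    q0 <- c(det$mu, best$par[free])
    H <- tryCatch(pracma::hessian(full, q0), error = function(e) NULL)
    if (!is.null(H)) {
      Vq <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vq)) {
        cand <- Vq[seq_len(d), seq_len(d), drop = FALSE]
        cand <- (cand + t(cand)) / 2
        if (all(is.finite(cand)) &&
            min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values) > 0) {
          cov_mu <- cand
          cov_src <- "information"
        }
      }
    }
  }
  dimnames(cov_mu) <- list(outcome_ids, outcome_ids)

  rho <- est$rho
  bflag <- abs(rho) > 1 - BOUNDARY_EPS
  diag(bflag) <- FALSE
  rho_rep <- rho
  rho_rep[bflag] <- sign(rho[bflag])
  dimnames(rho_rep) <- dimnames(bflag) <- list(outcome_ids, outcome_ids)

  mu <- setNames(det$mu, outcome_ids)
  se <- sqrt(diag(cov_mu))
  structure(list(
    model = model_label,
    outcome_ids = outcome_ids,
    mu = mu,
    cov_mu = cov_mu,
    cov_mu_source = cov_src,
    se_mu = se,
    tau = setNames(est$tau, outcome_ids),
    rho_between = rho_rep,
    ci_low = mu - qnorm(0.975) * se,
    ci_high = mu + qnorm(0.975) * se,
    status = policy$status,
    boundary_flags = bflag,
    n_starts_used = starts_used,
    n_studies = length(studies),
    loglik = -best$value,
    diagnostics = policy$diagnostics
  ), class = "mvma_fit")
}

mvma_failure <- function(outcome_ids, model_label, options, message, n_starts) {
  d <- length(outcome_ids)
  nav <- setNames(rep(NA_real_, d), outcome_ids)
  nam <- matrix(NA_real_, d, d, dimnames = list(outcome_ids, outcome_ids))
  structure(list(
    model = model_label, outcome_ids = outcome_ids,
    mu = nav, cov_mu = nam, cov_mu_source = "none", se_mu = nav,
    tau = nav, rho_between = nam, ci_low = nav, ci_high = nav,
    status = "failed_convergence",
    boundary_flags = matrix(FALSE, d, d, dimnames = list(outcome_ids, outcome_ids)),
    n_starts_used = n_starts, n_studies = NA_integer_, loglik = NA_real_,
    diagnostics = list(message = message)
  ), class = "mvma_fit")
}

# Quick per-outcome REML tau estimates used to initialise the optimizers.
init_tau <- function(studies, d) {
  tau <- numeric(d)
  for (j in seq_len(d)) {
    y <- c(); v <- c()
    for (st in studies) {
      pos <- match(j, st$idx)
      if (!is.na(pos)) { y <- c(y, st$y[pos]); v <- c(v, st$S[pos, pos]) }
    }
    if (length(y) >= 2L) {
      opt <- optimize(function(z) uvma_restricted_ll(exp(z), y, v),
                      interval = c(log(1e-10), log(max(10, 10 * stats::var(y)))),
                      maximum = TRUE, tol = 1e-8)
      tau[j] <- sqrt(exp(opt$maximum))
    }
    tau[j] <- max(tau[j], 0.05)
  }
  tau
}

#' Fully hierarchical multivariate random-effects meta-analysis (REML)
#'
#' Fits \eqn{y_i \sim N(\mu, S_i + \Sigma)} where \eqn{y_i} is study
#' \eqn{i}'s vector of observed log odds ratios, \eqn{S_i} its within-study
#' covariance matrix (variances plus analytically derived or externally
#' fixed within-study correlations) and \eqn{\Sigma} the between-study
#' covariance matrix, estimated by restricted maximum likelihood. Studies
#' with missing outcomes contribute the observed sub-vector and the
#' matching sub-matrix of \eqn{S_i + \Sigma}. \eqn{\Sigma} is parameterized
#' through its Cholesky factor with log-transformed diagonal; the summary
#' effects are profiled out by generalized least squares.
#'
#' @param effects data.frame from [derive_effects()].
#' @param within_cov list from [assemble_within_cov()]; every study with
#'   two or more observed outcomes must have a complete matrix (no
#'   `"unavailable"` entries) — otherwise use [fit_riley()].
#' @param options a [fit_options] object. `fix_correlations` holds
#'   between-study correlations fixed; `fix_tau` (with fully fixed
#'   correlations) reduces the fit to generalized least squares.
#' @param outcome_ids outcomes to fit (default: all in `effects`).
#' @return An object of class `mvma_fit`.
#' @export
fit_hierarchical <- function(effects, within_cov, options = fit_options(),
                             outcome_ids = NULL) {
  if (is.null(outcome_ids)) {
    outcome_ids <- unique(effects$outcome_id[!effects$missing])
  }
  d <- length(outcome_ids)
  if (d < 2L) stop("multivariate fit needs at least 2 outcomes")
  studies <- build_study_data(effects, outcome_ids, within_cov)
  check_min_reporting(studies, d, outcome_ids)
  for (st in studies) {
    if (length(st$idx) >= 2L && !is.null(st$source) &&
        any(st$source == "unavailable")) {
      stop(sprintf("study '%s' lacks a within-study correlation; the hierarchical model needs a complete S matrix (consider fit_riley)",
                   st$study_id))
    }
  }

  fixR <- options$fix_correlations
  fixT <- options$fix_tau
  tau0 <- init_tau(studies, d)

  if (is.null(fixR) && is.null(fixT)) {
    # free Sigma via Cholesky: theta = (log diag L, offdiag L column-wise)
    noff <- d * (d - 1L) / 2L
    init <- c(log(tau0), rep(0, noff))
    lower <- c(rep(LOG_SD_MIN, d), rep(-20, noff))
    upper <- c(rep(LOG_SD_MAX, d), rep(20, noff))
    make_Sigma <- function(theta) {
      L <- diag(exp(theta[seq_len(d)]), d)
      if (noff > 0L) L[lower.tri(L)] <- theta[-seq_len(d)]
      L %*% t(L)
    }
    extract <- function(theta) {
      Sg <- make_Sigma(theta)
      tau <- sqrt(diag(Sg))
      rho <- diag(d)
      pos <- tau > 1e-6
      if (sum(pos) >= 2L) {
        rho[pos, pos] <- stats::cov2cor(Sg[pos, pos, drop = FALSE] +
                                          diag(1e-300, sum(pos)))
      }
      list(tau = tau, rho = rho)
    }
    has_free_corr <- TRUE
    corr_idx <- NULL
  } else if (is.null(fixR) && !is.null(fixT)) {
    # between-study SDs fixed, correlations free (Fisher-z per pair)
    tauF <- fixT[outcome_ids]
    noff <- d * (d - 1L) / 2L
    init <- rep(0, noff)
    lower <- rep(-Z_MAX, noff); upper <- rep(Z_MAX, noff)
    make_Sigma <- function(theta) {
      R <- diag(d)
      R[upper.tri(R)] <- tanh(theta)
      R[lower.tri(R)] <- t(R)[lower.tri(R)]
      diag(tauF, d) %*% R %*% diag(tauF, d)
    }
    extract <- function(theta) {
      R <- diag(d)
      R[upper.tri(R)] <- tanh(theta)
      R[lower.tri(R)] <- t(R)[lower.tri(R)]
      list(tau = tauF, rho = R)
    }
    has_free_corr <- TRUE
    corr_idx <- seq_len(noff)
  } else {
    R <- fixR[outcome_ids, outcome_ids]
    if (any(is.na(R))) stop("fix_correlations for the hierarchical model must be complete over the fitted outcomes")
    if (is.null(fixT)) {
      init <- log(tau0); lower <- rep(LOG_SD_MIN, d); upper <- rep(LOG_SD_MAX, d)
      make_Sigma <- function(theta) {
        tau <- exp(theta)
        diag(tau, d) %*% R %*% diag(tau, d)
      }
      extract <- function(theta) list(tau = exp(theta), rho = R)
    } else {
      tauF <- fixT[outcome_ids]
      init <- numeric(0); lower <- numeric(0); upper <- numeric(0)
      make_Sigma <- function(theta) diag(tauF, d) %*% R %*% diag(tauF, d)
      extract <- function(theta) list(tau = tauF, rho = R)
    }
    has_free_corr <- FALSE
    corr_idx <- NULL
  }
  Vfun <- function(theta, st) {
    Sg <- make_Sigma(theta)
    st$S + Sg[st$idx, st$idx, drop = FALSE]
  }
  fit_mvma_engine(studies, outcome_ids, Vfun,
                  list(init = init, lower = lower, upper = upper,
                       extract = extract, has_free_corr = has_free_corr,
                       corr_idx = corr_idx),
                  options, "hierarchical")
}

#' Riley overall-correlation multivariate meta-analysis (REML)
#'
#' Fits the marginal multivariate model that does not require within-study
#' correlations: outcome \eqn{j} of study \eqn{i} has marginal variance
#' \eqn{s_{ij}^2 + \psi_j^2} and each outcome pair \eqn{(j,k)} within a
#' study has covariance \eqn{\rho_{jk}\sqrt{(s_{ij}^2+\psi_j^2)(s_{ik}^2+
#' \psi_k^2)}}, where \eqn{\rho_{jk}} is a single overall correlation per
#' pair amalgamating within- and between-study correlation and
#' \eqn{\psi_j} plays the role of the between-study SD. Correlations are
#' optimized on the Fisher-z scale; estimates within `1e-4` of ±1 are
#' reported at the boundary with a flag rather than treated as errors.
#'
#' @param effects data.frame from [derive_effects()]; only the variances
#'   are used (no within-study correlations are needed).
#' @param options a [fit_options] object. A complete `fix_correlations`
#'   matrix gives the fixed-correlation variant (`model = "riley_fixed"`),
#'   in which only \eqn{(\mu, \psi)} are estimated; `NA` entries stay free.
#' @param outcome_ids outcomes to fit (default: all in `effects`).
#' @param share_rho logical; if `TRUE` a single overall correlation is
#'   shared across all outcome pairs (default `FALSE`: one per pair).
#' @return An object of class `mvma_fit`.
#' @export
fit_riley <- function(effects, options = fit_options(), outcome_ids = NULL,
                      share_rho = FALSE) {
  if (is.null(outcome_ids)) {
    outcome_ids <- unique(effects$outcome_id[!effects$missing])
  }
  d <- length(outcome_ids)
  if (d < 2L) stop("multivariate fit needs at least 2 outcomes")
  studies <- build_study_data(effects, outcome_ids, within_cov = NULL)
  check_min_reporting(studies, d, outcome_ids)

  pairs <- which(upper.tri(diag(d)), arr.ind = TRUE)
  npair <- nrow(pairs)
  fixR <- options$fix_correlations
  rho_fixed <- rep(NA_real_, npair)
  if (!is.null(fixR)) {
    R <- fixR[outcome_ids, outcome_ids]
    rho_fixed <- R[upper.tri(R)]
  }
  free_pair <- is.na(rho_fixed)
  if (share_rho && any(free_pair)) {
    nz <- 1L
  } else {
    nz <- sum(free_pair)
  }

  fixT <- options$fix_tau
  free_psi <- is.null(fixT)
  tau0 <- init_tau(studies, d)
  npsi <- if (free_psi) d else 0L
  init <- c(if (free_psi) log(tau0), rep(0, nz))
  lower <- c(rep(LOG_SD_MIN, npsi), rep(-Z_MAX, nz))
  upper <- c(rep(LOG_SD_MAX, npsi), rep(Z_MAX, nz))

  build_R <- function(theta) {
    Rm <- diag(d)
    z <- if (nz > 0L) theta[npsi + seq_len(nz)] else numeric(0)
    rho_free <- if (share_rho && nz == 1L) {
      rep(tanh(z), sum(free_pair))
    } else {
      tanh(z)
    }
    vals <- rho_fixed
    vals[free_pair] <- rho_free
    for (q in seq_len(npair)) {
      Rm[pairs[q, 1L], pairs[q, 2L]] <- Rm[pairs[q, 2L], pairs[q, 1L]] <- vals[q]
    }
    Rm
  }
  get_psi <- function(theta) {
    if (free_psi) exp(theta[seq_len(d)]) else fixT[outcome_ids]
  }
  Vfun <- function(theta, st) {
    psi <- get_psi(theta)
    Rm <- build_R(theta)
    sd_tot <- sqrt(diag(st$S) + psi[st$idx]^2)
    Rm[st$idx, st$idx, drop = FALSE] * tcrossprod(sd_tot)
  }
  extract <- function(theta) list(tau = get_psi(theta), rho = build_R(theta))
  label <- if (!is.null(fixR) && !any(free_pair)) "riley_fixed" else "riley"
  fit_mvma_engine(studies, outcome_ids, Vfun,
                  list(init = init, lower = lower, upper = upper,
                       extract = extract, has_free_corr = any(free_pair),
                       corr_idx = if (nz > 0L) npsi + seq_len(nz)),
                  options, label)
}

check_min_reporting <- function(studies, d, outcome_ids) {
  counts <- integer(d)
  for (st in studies) counts[st$idx] <- counts[st$idx] + 1L
  if (any(counts < 2L)) {
    stop(sprintf("outcome '%s' has fewer than 2 reporting studies",
                 outcome_ids[which(counts < 2L)[1L]]))
  }
  invisible(counts)
}

#' @export
print.mvma_fit <- function(x, ...) {
  cat(sprintf("Multivariate random-effects meta-analysis (%s model)\n", x$model))
  cat(sprintf("  status: %s (starts used: %d)\n", x$status, x$n_starts_used))
  if (x$status == "converged") {
    for (j in seq_along(x$outcome_ids)) {
      cat(sprintf("  %s: OR %.3f (95%% CI %.3f-%.3f), tau %.3f\n",
                  x$outcome_ids[j], exp(x$mu[j]), exp(x$ci_low[j]),
                  exp(x$ci_high[j]), x$tau[j]))
    }
    off <- x$rho_between[upper.tri(x$rho_between)]
    if (length(off) > 0L) {
      cat("  correlations:", paste(sprintf("%.3f", off), collapse = ", "))
      if (any(x$boundary_flags)) cat("  [boundary]")
      cat("\n")
    }
  } else {
    cat(sprintf("  %s\n", x$diagnostics$message))
  }
  invisible(x)
}

#' Fit all outcome pairs and the full multivariate model for a dataset
#'
#' For every pair of eligible outcomes, fits the hierarchical model when a
#' complete within-study covariance is available for every study reporting
#' both outcomes (structural relations or supplied fixed within-study
#' correlations) and the Riley overall-correlation model otherwise; for
#' three or more eligible outcomes the full joint model is attempted the
#' same way. Per-fit convergence failures are recorded as statuses, never
#' raised, so one failing pair does not abort the rest.
#'
#' @param dataset a [meta_dataset].
#' @param options a [fit_options] object.
#' @param min_studies eligibility threshold (default 3 reporting studies).
#' @param fixed_within_corr optional within-study correlation matrix passed
#'   to [assemble_within_cov()] for structurally unrelated pairs.
#' @return list with `pairs` (named list of `mvma_fit`, names like
#'   `"bivariate(1,2)"`), `full` (`mvma_fit` or `NULL`), `eligibility`
#'   (the [eligibility_filter()] report), and `outcome_index` (mapping of
#'   outcome ids to the numeric labels used in names).
#' @export
fit_all_pairs <- function(dataset, options = fit_options(), min_studies = 3L,
                          fixed_within_corr = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  rep <- eligibility_filter(dataset, min_studies)
  oids <- rep$outcome_id[rep$eligible]
  if (length(oids) < 2L) stop("fewer than 2 eligible outcomes; multivariate analysis not applicable")
  effects <- derive_effects(dataset)
  within_cov <- assemble_within_cov(dataset, fixed_corr = fixed_within_corr)
  idx_map <- setNames(match(oids, dataset$outcome_ids), oids)

  pair_available <- function(a, b) {
    for (wc in within_cov) {
      if (all(c(a, b) %in% wc$outcome_ids)) {
        if (wc$source[a, b] == "unavailable") return(FALSE)
      }
    }
    TRUE
  }
  fit_one <- function(sel) {
    hier_ok <- TRUE
    for (j in seq_along(sel)) for (k in seq_along(sel)) {
      if (j < k && !pair_available(sel[j], sel[k])) hier_ok <- FALSE
    }
    res <- tryCatch({
      if (hier_ok) {
        fit_hierarchical(effects, within_cov, options, outcome_ids = sel)
      } else {
        fit_riley(effects, options, outcome_ids = sel)
      }
    }, error = function(e) {
      f <- mvma_failure(sel, if (hier_ok) "hierarchical" else "riley",
                        options, conditionMessage(e), 0L)
      f
    })
    res
  }

  pairs <- list()
  cmb <- utils::combn(oids, 2L)
  for (q in seq_len(ncol(cmb))) {
    sel <- cmb[, q]
    nm <- sprintf("bivariate(%d,%d)", idx_map[sel[1L]], idx_map[sel[2L]])
    pairs[[nm]] <- fit_one(sel)
  }
  full <- NULL
  if (length(oids) >= 3L) {
    full <- fit_one(oids)
  }
  list(pairs = pairs, full = full, eligibility = rep, outcome_index = idx_map)
}
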