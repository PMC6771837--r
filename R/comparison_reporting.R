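#' Side-by-side univariate vs multivariate comparison table
#'
#' Builds one row per (outcome, model) with summary odds ratios, 95%
#' confidence intervals, between-study SDs and a 5%-level significance
#' flag (Wald interval on the log OR scale excluding 0, equivalently the
#' OR-scale interval excluding 1; no multiplicity adjustment). Failed
#' multivariate fits are kept as rows with status `"failed_convergence"`
#' (rendered as FC), and outcomes present only in the multivariate fits
#' are labelled, not dropped. The attribute `"change_summary"` lists the
#' outcomes whose significance flag differs between the univariate fit and
#' any multivariate model — the paper-trail of conclusion changes.
#'
#' @param uv named list of `uvma_fit` objects (one per outcome).
#' @param mv list of `mvma_fit` objects, or the result of
#'   [fit_all_pairs()] (its `pairs` and `full` components are used; list
#'   names become model labels).
#' @return data.frame of class `comparison_table` with columns
#'   `outcome_id`, `model_label`, `or_estimate`, `ci_low_or`, `ci_high_or`,
#'   `tau`, `status`, `significant_5pct`; attribute `"change_summary"`.
#' @export
build_comparison <- function(uv, mv) {
  if (is.list(mv) && !is.null(mv$pairs)) {
    mvl <- mv$pairs
    if (!is.null(mv$full)) {
      mvl[[sprintf("%s(%s)",
                   if (length(mv$full$outcome_ids) == 3L) "trivariate" else "multivariate",
                   paste(mv$outcome_index[mv$full$outcome_ids], collapse = ","))]] <- mv$full
    }
  } else {
    mvl <- mv
    if (inherits(mvl, "mvma_fit")) mvl <- list(multivariate = mvl)
  }
  rows <- list()
  add_row <- function(oid, label, mu, lo, hi, tau, status) {
    sig <- if (status == "converged") (lo > 0 || hi < 0) else NA
    rows[[length(rows) + 1L]] <<- data.frame(
      outcome_id = oid, model_label = label,
      or_estimate = if (status == "converged") exp(mu) else NA_real_,
      ci_low_or = if (status == "converged") exp(lo) else NA_real_,
      ci_high_or = if (status == "converged") exp(hi) else NA_real_,
      tau = if (status == "converged") tau else NA_real_,
      status = status, significant_5pct = sig, stringsAsFactors = FALSE)
  }
  for (f in uv) {
    add_row(f$outcome_id, "univariate", f$mu, f$ci_low, f$ci_high, f$tau,
            f$status)
  }
  labels <- names(mvl)
  if (is.null(labels)) labels <- paste0("multivariate", seq_along(mvl))
  for (i in seq_along(mvl)) {
    f <- mvl[[i]]
    for (j in seq_along(f$outcome_ids)) {
      add_row(f$outcome_ids[j], labels[i], f$mu[j], f$ci_low[j], f$ci_high[j],
              f$tau[j], f$status)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  uv_oids <- vapply(uv, `[[`, character(1L), "outcome_id")
  changed <- character(0)
  for (oid in unique(tab$outcome_id)) {
    if (!oid %in% uv_oids) next
    uv_sig <- tab$significant_5pct[tab$outcome_id == oid &
                                     tab$model_label == "univariate"]
    mv_sig <- tab$significant_5pct[tab$outcome_id == oid &
                                     tab$model_label != "univariate"]
    mv_sig <- mv_sig[!is.na(mv_sig)]
    if (length(uv_sig) == 1L && !is.na(uv_sig) && any(mv_sig != uv_sig)) {
      changed <- c(changed, oid)
    }
  }
  attr(tab, "change_summary") <- changed
  class(tab) <- c("comparison_table", class(tab))
  tab
}

#' @export
print.comparison_table <- function(x, ...) {
  disp <- as.data.frame(x)
  disp$estimate <- ifelse(disp$status == "converged",
                          sprintf("%.2f (%.2f-%.2f) %.2f", disp$or_estimate,
                                  disp$ci_low_or, disp$ci_high_or, disp$tau),
                          "FC")
  print(disp[, c("outcome_id", "model_label", "estimate", "significant_5pct")],
        row.names = FALSE)
  ch <- attr(x, "change_summary")
  if (length(ch) > 0L) {
    cat("significance changed between univariate and multivariate for:",
        paste(ch, collapse = ", "), "\n")
  } else {
    cat("no significance changes between univariate and multivariate models\n")
  }
  invisible(x)
}

#' Contour-enhanced funnel plot data
#'
#' Returns per-study funnel coordinates (log OR against its standard
#' error) with each study classified into a two-sided significance band,
#' plus the contour polylines `effect = ±z_q · se` for the conventional
#' levels (p = 0.10, 0.05, 0.01). Asymmetry is left to visual inspection
#' and to the descriptive band counts from [funnel_band_counts()]; no test
#' statistic is computed by default.
#'
#' @param effects data.frame from [derive_effects()] for one outcome.
#' @param outcome_id optional outcome to select.
#' @param se_grid number of points per contour polyline.
#' @return list with `points` (data.frame `study_id`, `effect`, `se`,
#'   `contour_band`) and `contours` (data.frame `level`, `se`, `lower`,
#'   `upper`).
#' @export
funnel_data <- function(effects, outcome_id = NULL, se_grid = 50L) {
  if (!is.null(outcome_id)) {
    effects <- effects[effects$outcome_id == outcome_id, , drop = FALSE]
  }
  effects <- effects[!effects$missing, , drop = FALSE]
  if (nrow(effects) < 3L) stop("funnel diagnostics need at least 3 non-missing effects")
  if (length(unique(effects$outcome_id)) != 1L) {
    stop("effects span multiple outcomes; pass 'outcome_id'")
  }
  se <- sqrt(effects$var)
  z <- abs(effects$log_or) / se
  band <- cut(2 * pnorm(-z),
              breaks = c(-Inf, 0.01, 0.05, 0.10, Inf),
              labels = c("p<=0.01", "0.01<p<=0.05", "0.05<p<=0.10", "p>0.10"))
  points <- data.frame(study_id = effects$study_id, effect = effects$log_or,
                       se = se, contour_band = as.character(band),
                       stringsAsFactors = FALSE)
  se_seq <- seq(1e-6, max(se) * 1.05, length.out = se_grid)
  contours <- do.call(rbind, lapply(c(0.10, 0.05, 0.01), function(q) {
    zq <- qnorm(1 - q / 2)
    data.frame(level = q, se = se_seq, lower = -zq * se_seq,
               upper = zq * se_seq)
  }))
  list(points = points, contours = contours)
}

#' Descriptive funnel-band counts by study size
#'
#' Cross-tabulates the funnel significance bands against terciles of the
#' standard error (a proxy for study size): under selective reporting of
#' significant results in small studies, the high-significance bands are
#' over-represented in the large-SE tercile.
#'
#' @param funnel output of [funnel_data()].
#' @return contingency table of contour band by SE tercile.
#' @export
funnel_band_counts <- function(funnel) {
  p <- funnel$points
  ter <- cut(rank(p$se, ties.method = "first"),
             breaks = 3L, labels = c("large", "medium", "small"))
  table(band = p$contour_band, size = ter)
}

#' Egger-type regression test for funnel asymmetry
#'
#' Weighted regression of the effect on its standard error; off by default
#' in the reports because the primary assessment of asymmetry is visual.
#'
#' @param funnel output of [funnel_data()].
#' @return list with `intercept`, `slope`, `slope_se`, `p_value` (test of
#'   zero slope, i.e. no association between effect and precision).
#' @export
egger_regression <- function(funnel) {
  p <- funnel$points
  fit <- stats::lm(effect ~ se, data = p, weights = 1 / p$se^2)
  sm <- summary(fit)$coefficients
  list(intercept = sm[1L, 1L], slope = sm[2L, 1L], slope_se = sm[2L, 2L],
       p_value = sm[2L, 4L])
}

#' Write comparison tables and diagnostic figures
#'
#' Writes the comparison table as CSV (tabled values rounded to 2 decimals,
#' failed fits rendered `FC`) and as full-precision JSON, and — when a
#' graphics device is available — a forest plot per outcome (study effects
#' plus each model's summary) and a contour-enhanced funnel figure.
#'
#' @param rows a `comparison_table` from [build_comparison()].
#' @param funnel optional named list of [funnel_data()] outputs (one per
#'   outcome), or a single one.
#' @param dir output directory (created if absent).
#' @param effects optional data.frame from [derive_effects()]; required
#'   for the per-study points of the forest plots.
#' @param figures logical; attempt figure output (default `TRUE`).
#' @return invisibly, character vector of files written.
#' @export
render_reports <- function(rows, funnel = NULL, dir = ".", effects = NULL,
                           figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  disp <- as.data.frame(rows)
  fc <- disp$status != "converged"
  for (col in c("or_estimate", "ci_low_or", "ci_high_or", "tau")) {
    disp[[col]] <- ifelse(fc, "FC", sprintf("%.2f", disp[[col]]))
  }
  csv_path <- file.path(dir, "comparison.csv")
  write.csv(disp, csv_path, row.names = FALSE, quote = FALSE)
  written <- c(written, csv_path)

  json_path <- file.path(dir, "comparison.json")
  jsonlite::write_json(
    list(rows = as.data.frame(rows),
         change_summary = attr(rows, "change_summary")),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  written <- c(written, json_path)

  if (figures) {
    for (oid in unique(rows$outcome_id)) {
      fig <- forest_plot(rows, oid, effects = effects)
      path <- file.path(dir, sprintf("forest_%s.png", gsub("[^A-Za-z0-9_.-]", "_", oid)))
      ok <- try_save_figure(fig, path)
      if (ok) written <- c(written, path)
    }
    if (!is.null(funnel)) {
      if (!is.null(funnel$points)) funnel <- list(outcome = funnel)
      for (nm in names(funnel)) {
        fig <- funnel_plot(funnel[[nm]])
        path <- file.path(dir, sprintf("funnel_%s.png", gsub("[^A-Za-z0-9_.-]", "_", nm)))
        ok <- try_save_figure(fig, path)
        if (ok) written <- c(written, path)
      }
    }
  }
  invisible(written)
}

try_save_figure <- function(fig, path, width = 7, height = 5) {
  ok <- tryCatch({
    ggplot2::ggsave(path, fig, width = width, height = height, dpi = 150)
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Forest plot for one outcome across models
#'
#' @param rows a `comparison_table`.
#' @param outcome_id outcome to plot.
#' @param effects optional [derive_effects()] data.frame adding per-study
#'   points above the model summaries.
#' @return a ggplot object.
#' @export
forest_plot <- function(rows, outcome_id, effects = NULL) {
  sub <- rows[rows$outcome_id == outcome_id, , drop = FALSE]
  dat <- data.frame(label = sub$model_label, or = sub$or_estimate,
                    lo = sub$ci_low_or, hi = sub$ci_high_or,
                    status = sub$status, kind = "model summary",
                    stringsAsFactors = FALSE)
  if (!is.null(effects)) {
    es <- effects[effects$outcome_id == outcome_id & !effects$missing, ,
                  drop = FALSE]
    if (nrow(es) > 0L) {
      z <- qnorm(0.975) * sqrt(es$var)
      dat <- rbind(data.frame(label = paste0("study ", es$study_id),
                              or = exp(es$log_or), lo = exp(es$log_or - z),
                              hi = exp(es$log_or + z), status = "converged",
                              kind = "study", stringsAsFactors = FALSE),
                   dat)
    }
  }
  dat$label <- factor(dat$label, levels = rev(dat$label))
  fcs <- dat$status != "converged"
  p <- ggplot2::ggplot(dat[!fcs, ],
                       ggplot2::aes(x = or, y = label, shape = kind)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lo, xmax = hi), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  title = sprintf("Outcome %s", outcome_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (any(fcs)) {
    p <- p + ggplot2::geom_text(data = dat[fcs, ],
                                ggplot2::aes(x = 1, y = label, label = "FC"),
                                inherit.aes = FALSE)
  }
  p
}

#' Contour-enhanced funnel plot
#'
#' @param funnel output of [funnel_data()].
#' @return a ggplot object with inverted SE axis and shaded significance
#'   contours.
#' @export
funnel_plot <- function(funnel) {
  cont <- funnel$contours
  pts <- funnel$points
  ggplot2::ggplot() +
    ggplot2::geom_line(data = cont,
                       ggplot2::aes(x = lower, y = se, group = level),
                       linetype = 3, colour = "grey40") +
    ggplot2::geom_line(data = cont,
                       ggplot2::aes(x = upper, y = se, group = level),
                       linetype = 3, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = effect, y = se, colour = contour_band),
                        size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log odds ratio", y = "standard error",
                  colour = "two-sided p") +
    ggplot2::theme_minimal()
}
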