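#' Evaluate indirect predictions against benchmark GEBV
#'
#' Computes the agreement statistics for one replicate and one scenario:
#' Pearson and Spearman correlations, intercept `b0` and slope `b1` of the
#' OLS regression of GEBV on IP (slope 1 = no inflation/deflation), RMSE of
#' the difference, mean standardized bias
#' `(mean(IP) - mean(GEBV)) / sqrt(sigma2_a)` in additive-genetic-SD units,
#' and the variance ratio `var(GEBV) / var(IP)`. 95% confidence intervals
#' use the Fisher z transform for the correlations and t intervals for the
#' regression coefficients. Sample (n-1) variances throughout.
#'
#' @param gebv benchmark GEBV of the validation candidates.
#' @param ip indirect predictions of the same animals, same order.
#' @param sigma2_a additive genetic variance used to standardize the bias
#'   (default 0.25, the true simulation value).
#' @return one-row data.frame of class `eval_report` with the seven
#'   statistics; per-statistic 95% CIs in `attr(, "ci")`.
#' @export
evaluate_predictions <- function(gebv, ip, sigma2_a = 0.25) {
  n <- length(gebv)
  stopifnot(n == length(ip), n >= 3)
  if (stats::var(ip) <= 0) stop("zero-variance IP")
  pearson <- stats::cor(gebv, ip)
  spearman <- stats::cor(gebv, ip, method = "spearman")
  fit <- stats::lm(gebv ~ ip)
  b <- stats::coef(fit)
  rmse <- sqrt(mean((gebv - ip)^2))
  std_bias <- (mean(ip) - mean(gebv)) / sqrt(sigma2_a)
  var_ratio <- stats::var(gebv) / stats::var(ip)
  ci_cor <- function(r) {
    z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
    se <- 1 / sqrt(n - 3)
    tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  ci_b <- tryCatch(suppressWarnings(stats::confint(fit)),
                   error = function(e) matrix(NA_real_, 2, 2))
  out <- data.frame(pearson = pearson, spearman = spearman,
                    b0 = unname(b[1]), b1 = unname(b[2]),
                    rmse = rmse, std_bias = std_bias, var_ratio = var_ratio)
  attr(out, "ci") <- list(pearson = ci_cor(pearson),
                          spearman = ci_cor(spearman),
                          b0 = ci_b[1, ], b1 = ci_b[2, ])
  class(out) <- c("eval_report", class(out))
  out
}

#' Aggregate evaluation reports across replicates
#'
#' Statistics are computed per replicate and then averaged (never pooled):
#' the summary reports, per scenario and statistic, the cross-replicate
#' mean, the standard error `sd / sqrt(n_replicates)` (`NA` with a single
#' replicate), and the average of the per-replicate 95% CI bounds where
#' available.
#'
#' @param reports data.frame with columns `replicate`, `scenario` and the
#'   [evaluate_predictions()] statistics; `ci_low`/`ci_high` columns (long
#'   per-statistic rows) are produced by [reports_long()].
#' @return data.frame `scenario`, `statistic`, `mean`, `se`, `ci_low`,
#'   `ci_high`, scenarios ordered by error rate.
#' @export
aggregate_replicates <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  long <- reports_long(reports)
  groups <- split(long, list(long$scenario, long$statistic), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) data.frame(
    scenario = g$scenario[1], statistic = g$statistic[1],
    mean = mean(g$value),
    se = if (nrow(g) < 2) NA_real_ else stats::sd(g$value) / sqrt(nrow(g)),
    ci_low = mean(g$ci_low), ci_high = mean(g$ci_high))))
  rownames(out) <- NULL
  out[order(match(out$scenario, scenario_order(out$scenario)),
            match(out$statistic, stat_order())), , drop = FALSE]
}

stat_order <- function() c("pearson", "spearman", "b0", "b1",
                           "rmse", "std_bias", "var_ratio")

scenario_order <- function(scen) {
  u <- unique(as.character(scen))
  u[order(ifelse(u == "correct", -1,
                 suppressWarnings(as.numeric(sub("^E", "", u)))))]
}

# One row per replicate x scenario x statistic, carrying CI bounds where the
# per-replicate report provided them.
reports_long <- function(reports) {
  stats_cols <- intersect(stat_order(), names(reports))
  do.call(rbind, lapply(seq_len(nrow(reports)), function(i) {
    ci <- attr(reports, "ci_list")[[i]]
    data.frame(replicate = reports$replicate[i],
               scenario = reports$scenario[i],
               statistic = stats_cols,
               value = as.numeric(reports[i, stats_cols]),
               ci_low = vapply(stats_cols, function(s)
                 if (!is.null(ci) && !is.null(ci[[s]])) ci[[s]][1]
                 else NA_real_, 0),
               ci_high = vapply(stats_cols, function(s)
                 if (!is.null(ci) && !is.null(ci[[s]])) ci[[s]][2]
                 else NA_real_, 0),
               row.names = NULL)
  }))
}

#' Render the scenario summary as accuracy and bias tables
#'
#' Produces the two standard views: an accuracy table (correlations plus
#' the regression of GEBV on IP) and an error table (RMSE, standardized
#' bias, variance ratio), one row per scenario in
#' `correct, E05, E10, E20` order, entries formatted `mean +/- SE`.
#'
#' @param summary output of [aggregate_replicates()].
#' @param digits digits for the formatted entries.
#' @return list with data.frames `correlations` and `errors`, plus the
#'   underlying `summary`.
#' @export
render_tables <- function(summary, digits = 2) {
  fmt <- function(scen, stat) {
    row <- summary[summary$scenario == scen & summary$statistic == stat, ]
    if (nrow(row) == 0) return(NA_character_)
    se <- if (is.na(row$se)) "" else sprintf(" ± %.*f", digits, row$se)
    sprintf("%.*f%s", digits, row$mean, se)
  }
  scen <- scenario_order(summary$scenario)
  t1 <- data.frame(scenario = scen,
                   pearson = vapply(scen, fmt, "", stat = "pearson"),
                   spearman = vapply(scen, fmt, "", stat = "spearman"),
                   b0 = vapply(scen, fmt, "", stat = "b0"),
                   b1 = vapply(scen, fmt, "", stat = "b1"),
                   row.names = NULL)
  t2 <- data.frame(scenario = scen,
                   rmse = vapply(scen, fmt, "", stat = "rmse"),
                   std_bias = vapply(scen, fmt, "", stat = "std_bias"),
                   var_ratio = vapply(scen, fmt, "", stat = "var_ratio"),
                   row.names = NULL)
  list(correlations = t1, errors = t2, summary = summary)
}
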